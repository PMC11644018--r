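#' Clusters (nets) of hydrogen-bonded molecules
#'
#' Connected components of the undirected graph whose edges are the bonded
#' unordered pairs; molecules with no bond are singleton clusters.  Clusters
#' are labelled in order of their smallest member index so the partition is
#' deterministic.
#'
#' @param bonds bond table from [detect_bonds()].
#' @param n_molecules total molecule count.
#' @return list of integer vectors (sorted member indices), covering all
#'   molecules exactly once.
#' @export
hb_clusters <- function(bonds, n_molecules) {
  g <- igraph::make_empty_graph(n = n_molecules, directed = FALSE)
  if (nrow(bonds) > 0) {
    edges <- unique(cbind(pmin(bonds$donor, bonds$acceptor),
                          pmax(bonds$donor, bonds$acceptor)))
    g <- igraph::add_edges(g, t(edges))
  }
  memb <- igraph::components(g)$membership
  parts <- unname(split(seq_len(n_molecules), memb))
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, min, numeric(1)))]
}

#' Patches: connected components of four-bonded molecules
#'
#' A patch is a connected component of the subgraph induced on molecules
#' with at least `min_bonds` hydrogen bonds (counting bond records, donor
#' and acceptor roles alike), using only bonds between two such molecules.
#'
#' @inheritParams hb_clusters
#' @param min_bonds degree threshold; default 4 ("four-bonded"), read as
#'   `>= 4` so occasional five-bonded molecules do not fragment a patch.
#' @return list of integer vectors (possibly empty), each a patch.
#' @export
hb_patches <- function(bonds, n_molecules, min_bonds = 4) {
  counts <- nhb_counts(bonds, n_molecules)$counts
  four <- which(counts >= min_bonds)
  if (length(four) == 0) return(list())
  keep <- bonds$donor %in% four & bonds$acceptor %in% four
  sub <- bonds[keep, , drop = FALSE]
  idx <- match(seq_len(n_molecules), four)  # NA for non-members
  g <- igraph::make_empty_graph(n = length(four), directed = FALSE)
  if (nrow(sub) > 0) {
    edges <- unique(cbind(pmin(idx[sub$donor], idx[sub$acceptor]),
                          pmax(idx[sub$donor], idx[sub$acceptor])))
    g <- igraph::add_edges(g, t(edges))
  }
  memb <- igraph::components(g)$membership
  parts <- unname(split(four, memb))
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, min, numeric(1)))]
}

#' Degree-of-connectivity parameter P_g
#'
#' Default (`mode = "molecule"`): the fraction of molecules engaged in
#' clusters of at least `min_size` hydrogen-bonded molecules.  The variant
#' (`mode = "cluster"`): the probability that a randomly chosen cluster
#' contains at least `min_size` molecules.  Both printed definitions are
#' kept; the mode used is always recorded in the result.
#'
#' @param clusters cluster partition from [hb_clusters()].
#' @param mode `"molecule"` or `"cluster"`.
#' @param min_size cluster-size threshold (default 5).
#' @return numeric in `[0, 1]` with attribute `mode`.
#' @export
pg <- function(clusters, mode = c("molecule", "cluster"), min_size = 5) {
  mode <- match.arg(mode)
  sizes <- lengths(clusters)
  if (sum(sizes) < 1) stop("empty partition")
  val <- switch(mode,
    molecule = sum(sizes[sizes >= min_size]) / sum(sizes),
    cluster = sum(sizes >= min_size) / length(sizes))
  structure(val, mode = mode)
}

#' Per-frame connectivity statistics
#'
#' @param frame an [hb_frame()].
#' @param bonds bond table for that frame.
#' @param pg_mode passed to [pg()].
#' @return list of class `connectivity_stats`: `clusters`, `patches`,
#'   `cluster_sizes`, `p_g`, `mean_nhb`, `n_monomers`.
#' @export
connectivity_stats <- function(frame, bonds, pg_mode = "molecule") {
  cl <- hb_clusters(bonds, frame$n_mol)
  pa <- hb_patches(bonds, frame$n_mol)
  structure(list(clusters = cl, patches = pa, cluster_sizes = lengths(cl),
                 p_g = pg(cl, mode = pg_mode),
                 mean_nhb = nhb_counts(bonds, frame$n_mol)$mean_nhb,
                 n_monomers = length(detect_monomers(frame, bonds))),
            class = "connectivity_stats")
}
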