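#' Triple hydrogen-bond criterion
#'
#' A donor-H..acceptor arrangement is a hydrogen bond iff all three hold
#' (strict inequalities): pair interaction energy `E < e_max`, H..O distance
#' `R < r_max`, and donor OH inclination to the O-O line `alpha < alpha_max`.
#'
#' @param e_max pair-energy threshold (kJ/mol, negative).
#' @param r_max H..O distance threshold (nm).
#' @param alpha_max angle threshold (degrees, in (0, 90)); the more linear
#'   variant uses 20.
#' @return list of class `hb_criteria`.
#' @export
hb_criteria <- function(e_max = -8, r_max = 0.25, alpha_max = 30) {
  if (!(r_max > 0)) stop("r_max must be positive")
  if (!(alpha_max > 0 && alpha_max < 90)) stop("alpha_max must be in (0, 90)")
  if (!(e_max < 0)) stop("e_max must be negative")
  structure(list(e_max = e_max, r_max = r_max, alpha_max = alpha_max),
            class = "hb_criteria")
}

.mol_rows <- function(m) (3L * m - 2L):(3L * m)

#' Intermolecular pair interaction energy
#'
#' Sum of all nine site-site Coulomb terms (minimum image, no cutoff) plus
#' the short-range terms of the same potential (Lennard-Jones O-O and the
#' steep O-H repulsion); symmetric in `i, j`.  With `coulomb_only = TRUE`
#' the short-range terms are omitted - the mode for third-party
#' trajectories analysed without a known potential.
#'
#' @param frame an [hb_frame()].
#' @param i,j molecule indices (1-based, `i != j`).
#' @param potential an [water_potential()].
#' @param coulomb_only logical.
#' @return energy in kJ/mol.
#' @export
pair_interaction_energy <- function(frame, i, j, potential = water_potential(),
                                    coulomb_only = FALSE) {
  stopifnot(inherits(frame, "hb_frame"), i != j)
  if (i > j) { tmp <- i; i <- j; j <- tmp }  # canonical order: exact symmetry
  a <- frame$xyz[.mol_rows(i), , drop = FALSE]
  b <- frame$xyz[.mol_rows(j), , drop = FALSE]
  q <- c(potential$q_o, potential$q_h, potential$q_h)
  e <- 0
  for (s1 in 1:3) for (s2 in 1:3) {
    d <- minimum_image(a[s1, ] - b[s2, ], frame$box_length)
    r <- sqrt(sum(d^2))
    if (r < 0.01) stop("site overlap between molecules ", i, " and ", j)
    e <- e + .ke_coulomb * q[s1] * q[s2] / r
    if (!coulomb_only && xor(s1 == 1, s2 == 1))
      e <- e + potential$c_ohrep / r^16
  }
  if (!coulomb_only) {
    d <- minimum_image(a[1, ] - b[1, ], frame$box_length)
    r <- sqrt(sum(d^2))
    sr6 <- (potential$lj_sigma / r)^6
    e <- e + 4 * potential$lj_eps * (sr6^2 - sr6)
  }
  e
}

#' Hydrogen-bond geometry of a donor-H..acceptor candidate
#'
#' @param frame an [hb_frame()].
#' @param donor,acceptor molecule indices.
#' @param h_index donor hydrogen (1 or 2).
#' @return named vector: `r_oh` (nm, minimum-image H..O_acceptor distance)
#'   and `alpha` (degrees, inclination of the donor OH bond to the O-O line).
#' @export
hb_geometry <- function(frame, donor, h_index, acceptor) {
  stopifnot(inherits(frame, "hb_frame"), h_index %in% c(1, 2),
            donor != acceptor)
  o_d <- frame$xyz[3 * donor - 2, ]
  h <- frame$xyz[3 * donor - 2 + h_index, ]
  o_a <- frame$xyz[3 * acceptor - 2, ]
  L <- frame$box_length
  v_oh <- h - o_d                       # intramolecular, kept whole
  v_oo <- minimum_image(o_a - o_d, L)
  d_oo <- sqrt(sum(v_oo^2))
  if (d_oo < 1e-9) stop("coincident oxygen positions")
  r_oh <- sqrt(sum(minimum_image(o_a - h, L)^2))
  cosa <- sum(v_oh * v_oo) / (sqrt(sum(v_oh^2)) * d_oo)
  cosa <- min(1, max(-1, cosa))
  c(r_oh = r_oh, alpha = acos(cosa) * 180 / pi)
}

#' Detect hydrogen bonds in a frame
#'
#' Applies the triple criterion to every (donor, H, acceptor) candidate.
#' Candidates are restricted by an O-O distance prefilter at
#' `r_max + 0.12` nm (the maximum intramolecular O-H reach), which cannot
#' exclude a qualifying pair because `R_OH < r_max` forces
#' `d_OO <= R_OH + |OH| < r_max + 0.12`.
#'
#' @param frame an [hb_frame()].
#' @param criteria an [hb_criteria()].
#' @param potential an [water_potential()] used for the energetic criterion.
#' @param coulomb_only passed to [pair_interaction_energy()].
#' @param prefilter logical; disable to force the exhaustive all-triples scan.
#' @return data.frame with one row per bond: `donor`, `h_index`, `acceptor`,
#'   `r_oh`, `alpha`, `e_pair`.
#' @export
detect_bonds <- function(frame, criteria = hb_criteria(),
                         potential = water_potential(),
                         coulomb_only = FALSE, prefilter = TRUE) {
  stopifnot(inherits(frame, "hb_frame"), inherits(criteria, "hb_criteria"))
  n <- frame$n_mol
  empty <- data.frame(donor = integer(), h_index = integer(),
                      acceptor = integer(), r_oh = numeric(),
                      alpha = numeric(), e_pair = numeric())
  if (n < 2) return(empty)
  o_idx <- 3 * seq_len(n) - 2
  o_pos <- frame$xyz[o_idx, , drop = FALSE]
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  if (prefilter) {
    d <- minimum_image(o_pos[pairs[, 1], , drop = FALSE] -
                         o_pos[pairs[, 2], , drop = FALSE],
                       frame$box_length)
    keep <- rowSums(d^2) < (criteria$r_max + 0.12)^2
    pairs <- pairs[keep, , drop = FALSE]
  }
  rows <- list()
  e_cache <- new.env()
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    e_pair <- NA_real_
    for (cand in list(c(i, j), c(j, i))) {
      don <- cand[1]; acc <- cand[2]
      for (h in 1:2) {
        g <- hb_geometry(frame, don, h, acc)
        if (g["r_oh"] >= criteria$r_max) next
        if (g["alpha"] >= criteria$alpha_max) next
        if (is.na(e_pair))
          e_pair <- pair_interaction_energy(frame, i, j, potential,
                                            coulomb_only = coulomb_only)
        if (e_pair >= criteria$e_max) next
        rows[[length(rows) + 1L]] <-
          data.frame(donor = don, h_index = h, acceptor = acc,
                     r_oh = unname(g["r_oh"]), alpha = unname(g["alpha"]),
                     e_pair = e_pair)
      }
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Monomers: molecules forming no hydrogen bond
#'
#' @param frame the frame the bonds were detected in.
#' @param bonds a bond table from [detect_bonds()].
#' @return integer vector of molecule indices appearing in no bond as donor
#'   or acceptor.
#' @export
detect_monomers <- function(frame, bonds) {
  setdiff(seq_len(frame$n_mol), unique(c(bonds$donor, bonds$acceptor)))
}

#' Per-molecule hydrogen-bond counts and their mean
#'
#' A molecule's count is the number of bond records it appears in (donor or
#' acceptor role); two records on the same unordered pair count separately.
#'
#' @param bonds bond table from [detect_bonds()].
#' @param n_molecules total molecule count.
#' @return list: `counts` (integer vector) and `mean_nhb`.
#' @export
nhb_counts <- function(bonds, n_molecules) {
  counts <- tabulate(c(bonds$donor, bonds$acceptor), nbins = n_molecules)
  list(counts = counts, mean_nhb = mean(counts))
}

#' Detect bonds across a trajectory and build boolean time series
#'
#' Bond identity for the pair-level series is the unordered molecule pair: a
#' pair is "bonded" in a frame iff at least one donor-H..acceptor record
#' links it, so a donor switching hydrogens keeps the bond present.
#'
#' @param traj an [hb_trajectory()].
#' @inheritParams detect_bonds
#' @return list of class `bond_series`: `bonds` (per-frame bond tables),
#'   `pair_states` (logical pairs x frames matrix with rownames "i-j"),
#'   `monomer_states` (logical molecules x frames), `dt`, `n_mol`.
#' @export
detect_bonds_trajectory <- function(traj, criteria = hb_criteria(),
                                    potential = water_potential(),
                                    coulomb_only = FALSE) {
  stopifnot(inherits(traj, "hb_trajectory"))
  per_frame <- lapply(traj$frames, detect_bonds, criteria = criteria,
                      potential = potential, coulomb_only = coulomb_only)
  n_frames <- length(per_frame)
  n_mol <- traj$n_mol
  keys <- lapply(per_frame, function(b) {
    if (nrow(b) == 0) return(character())
    unique(paste(pmin(b$donor, b$acceptor), pmax(b$donor, b$acceptor),
                 sep = "-"))
  })
  all_keys <- sort(unique(unlist(keys)))
  pair_states <- matrix(FALSE, nrow = length(all_keys), ncol = n_frames,
                        dimnames = list(all_keys, NULL))
  monomer_states <- matrix(TRUE, nrow = n_mol, ncol = n_frames)
  for (f in seq_len(n_frames)) {
    if (length(keys[[f]])) pair_states[keys[[f]], f] <- TRUE
    b <- per_frame[[f]]
    monomer_states[unique(c(b$donor, b$acceptor)), f] <- FALSE
  }
  structure(list(bonds = per_frame, pair_states = pair_states,
                 monomer_states = monomer_states, dt = traj$dt,
                 n_mol = n_mol, criteria = criteria,
                 coulomb_only = coulomb_only),
            class = "bond_series")
}
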