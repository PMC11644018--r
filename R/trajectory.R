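#' Construct a single water frame
#'
#' A frame holds the coordinates of `n` 3-site water molecules in a periodic
#' cubic box.  Atoms are ordered as consecutive O,H,H triplets; coordinates
#' are in nm and need not be wrapped into the box (all distances go through
#' [minimum_image()], so wrapped and unwrapped inputs are equivalent).
#'
#' @param xyz numeric matrix (3*n_mol rows, 3 columns) of positions in nm,
#'   rows ordered O,H,H per molecule.
#' @param box_length box edge in nm.
#' @param time frame time stamp in fs.
#' @return object of class `hb_frame`.
#' @export
hb_frame <- function(xyz, box_length, time = 0) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("xyz must have 3 columns")
  if (nrow(xyz) %% 3 != 0) stop("row count must be a multiple of 3 (O,H,H triplets)")
  if (nrow(xyz) < 3) stop("frame must contain at least one molecule")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (!is.numeric(box_length) || length(box_length) != 1 || box_length <= 0)
    stop("box_length must be a single positive number")
  structure(list(xyz = unname(xyz), box_length = box_length, time = time,
                 n_mol = nrow(xyz) %/% 3L),
            class = "hb_frame")
}

#' @export
print.hb_frame <- function(x, ...) {
  cat(sprintf("<hb_frame> %d molecules, box %.4f nm, t = %g fs\n",
              x$n_mol, x$box_length, x$time))
  invisible(x)
}

#' Construct a trajectory from a list of frames
#'
#' @param frames list of [hb_frame()] objects with strictly increasing,
#'   equally spaced time stamps and identical molecule count and box.
#' @param metadata optional named list (e.g. state point `T_K`, `P_MPa`,
#'   `rho_kg_L`).
#' @return object of class `hb_trajectory` with element `dt` (fs).
#' @export
hb_trajectory <- function(frames, metadata = list()) {
  if (length(frames) < 1) stop("trajectory needs at least one frame")
  stopifnot(all(vapply(frames, inherits, logical(1), "hb_frame")))
  n <- vapply(frames, function(f) f$n_mol, integer(1))
  if (length(unique(n)) != 1) stop("all frames must share the molecule count")
  b <- vapply(frames, function(f) f$box_length, numeric(1))
  if (diff(range(b)) > 1e-9) stop("all frames must share the box length")
  times <- vapply(frames, function(f) f$time, numeric(1))
  dt <- NA_real_
  if (length(times) > 1) {
    d <- diff(times)
    if (any(d <= 0)) stop("frame times must be strictly increasing")
    if (diff(range(d)) > 1e-6 * max(d)) stop("frame spacing must be constant")
    dt <- d[1]
  }
  structure(list(frames = frames, dt = dt, n_mol = n[1], box_length = b[1],
                 metadata = metadata),
            class = "hb_trajectory")
}

#' @export
print.hb_trajectory <- function(x, ...) {
  cat(sprintf("<hb_trajectory> %d frames, %d molecules, dt = %g fs, box %.4f nm\n",
              length(x$frames), x$n_mol, x$dt, x$box_length))
  invisible(x)
}

#' @export
length.hb_trajectory <- function(x) length(x$frames)

#' Minimum-image convention for a periodic cubic box
#'
#' Maps each displacement component into `(-box/2, +box/2]`.
#'
#' @param d numeric vector or matrix of displacement components (nm).
#' @param box_length box edge (nm).
#' @return mapped displacement, same shape as `d`.
#' @export
minimum_image <- function(d, box_length) {
  if (box_length <= 0) stop("box_length must be positive")
  out <- d - box_length * round(d / box_length)
  # round() halves ties to even; force the half-open convention (-L/2, L/2]
  out[out <= -box_length / 2] <- out[out <= -box_length / 2] + box_length
  out[out > box_length / 2] <- out[out > box_length / 2] - box_length
  out
}

#' Write a trajectory as extended-XYZ
#'
#' One block per frame: atom count, then a comment line carrying
#' `Lattice="L 0 0 0 L 0 0 0 L" Properties=species:S:1:pos:R:3 time=<fs>`,
#' then one `O`/`H` line per atom.  Coordinates are written in nm with 12
#' significant digits so the round trip is lossless to analysis precision.
#'
#' @param traj an [hb_trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "hb_trajectory"))
  if (length(traj$frames) == 0) stop("refusing to write an empty trajectory")
  con <- file(path, "w")
  on.exit(close(con))
  species <- rep(c("O", "H", "H"), traj$n_mol)
  for (f in traj$frames) {
    writeLines(as.character(nrow(f$xyz)), con)
    writeLines(sprintf(
      'Lattice="%.12g 0 0 0 %.12g 0 0 0 %.12g" Properties=species:S:1:pos:R:3 time=%.12g',
      f$box_length, f$box_length, f$box_length, f$time), con)
    writeLines(sprintf("%s %.12g %.12g %.12g", species,
                       f$xyz[, 1], f$xyz[, 2], f$xyz[, 3]), con)
  }
  invisible(path)
}

#' Read an extended-XYZ water trajectory
#'
#' Parses the dialect written by [write_trajectory()]: per-frame
#' `Lattice="..."` (cubic) or `box=L` plus `time=t` keys in the comment
#' line.  Atoms must form consecutive O,H,H triplets; any other ordering is
#' an error naming the offending frame.
#'
#' @param path file path.
#' @param metadata optional metadata list attached to the trajectory.
#' @return an [hb_trajectory()].
#' @export
read_trajectory <- function(path, metadata = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  fidx <- 0L
  while (i <= length(lines)) {
    if (!grepl("\\S", lines[i])) { i <- i + 1L; next }
    fidx <- fidx + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat <= 0)
      stop(sprintf("frame %d: malformed atom-count line", fidx))
    if (i + 1L + nat > length(lines))
      stop(sprintf("frame %d: truncated frame (%d atom lines expected)", fidx, nat))
    comment <- lines[i + 1L]
    box <- NA_real_
    m <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]]
    if (length(m) == 2) {
      lat <- as.numeric(strsplit(trimws(m[2]), "\\s+")[[1]])
      if (length(lat) != 9) stop(sprintf("frame %d: malformed Lattice", fidx))
      diag3 <- lat[c(1, 5, 9)]
      off <- lat[-c(1, 5, 9)]
      if (any(abs(off) > 1e-9) || diff(range(diag3)) > 1e-9)
        stop(sprintf("frame %d: only cubic boxes are supported", fidx))
      box <- diag3[1]
    } else {
      m2 <- regmatches(comment, regexec("box=([0-9.eE+-]+)", comment))[[1]]
      if (length(m2) == 2) box <- as.numeric(m2[2])
    }
    if (is.na(box)) stop(sprintf("frame %d: missing box (Lattice= or box=)", fidx))
    tm <- regmatches(comment, regexec("[Tt]ime=([0-9.eE+-]+)", comment))[[1]]
    time <- if (length(tm) == 2) as.numeric(tm[2]) else NA_real_
    if (is.na(time)) stop(sprintf("frame %d: missing time= key", fidx))
    atom_lines <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(atom_lines), "\\s+")
    if (any(lengths(parts) < 4))
      stop(sprintf("frame %d: malformed atom line", fidx))
    species <- vapply(parts, `[`, character(1), 1L)
    expected <- rep(c("O", "H", "H"), length.out = nat)
    if (nat %% 3 != 0 || !all(species == expected))
      stop(sprintf("frame %d: atoms must be ordered as O,H,H per molecule", fidx))
    xyz <- matrix(as.numeric(vapply(parts, function(p) p[2:4], character(3))),
                  ncol = 3, byrow = TRUE)
    if (any(!is.finite(xyz)))
      stop(sprintf("frame %d: non-numeric coordinates", fidx))
    frames[[fidx]] <- hb_frame(xyz, box, time)
    i <- i + 2L + nat
  }
  if (fidx == 0) stop("no frames found in ", path)
  nmols <- vapply(frames, function(f) f$n_mol, integer(1))
  if (length(unique(nmols)) != 1) stop("inconsistent atom counts across frames")
  hb_trajectory(frames, metadata = metadata)
}
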