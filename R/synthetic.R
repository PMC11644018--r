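#' Specify a planted hydrogen-bond motif
#'
#' Motifs provide frames whose bond content is known by construction:
#' `dimer` (one donor aimed at one acceptor with exact H..O distance and OH
#' inclination), `pentamer` (a central molecule donating two and accepting
#' two bonds in tetrahedral arrangement), `lattice` (a diamond-cubic,
#' ice-like periodic network in which every molecule is four-bonded), and
#' `monomer_gas` (molecules so far apart that no pair can be bonded).
#'
#' @param kind one of `"dimer"`, `"pentamer"`, `"lattice"`, `"monomer_gas"`.
#' @param r_oh dimer H..O target distance (nm).
#' @param alpha dimer OH inclination angle (degrees, in `[0, 180)`).
#' @param o_o O-O distance of pentamer/lattice bonds (nm).
#' @param spacing monomer-gas grid spacing (nm); all intermolecular O..H
#'   separations exceed `spacing - 2 * r_intra`.
#' @param count number of molecules (monomer_gas) or lattice cells per edge.
#' @param box_length box edge (nm); defaults chosen per motif.
#' @return list of class `motif_spec`.
#' @export
motif_spec <- function(kind = c("dimer", "pentamer", "lattice", "monomer_gas"),
                       r_oh = 0.19, alpha = 5, o_o = 0.295, spacing = 0.7,
                       count = 27, box_length = NULL) {
  kind <- match.arg(kind)
  stopifnot(r_oh > 0, o_o > 0, spacing > 0, count >= 1)
  if (alpha < 0 || alpha >= 180) stop("alpha must be in [0, 180) degrees")
  if (is.null(box_length)) {
    box_length <- switch(kind,
      dimer = 3, pentamer = 3,
      lattice = count * 4 * o_o / sqrt(3),
      monomer_gas = ceiling(count^(1 / 3)) * spacing)
  }
  if (box_length <= 0) stop("box_length must be positive")
  min_extent <- switch(kind, dimer = 2 * (r_oh + 0.2), pentamer = 4 * o_o,
                       lattice = box_length, monomer_gas = box_length)
  if (box_length < min_extent)
    stop("box too small to contain the motif under minimum image")
  structure(list(kind = kind, r_oh = r_oh, alpha = alpha, o_o = o_o,
                 spacing = spacing, count = as.integer(count),
                 box_length = box_length),
            class = "motif_spec")
}

# unit vector
.unit <- function(v) v / sqrt(sum(v^2))

# two H positions around an O with bisector direction u, in the plane (u, w)
.acceptor_h <- function(o_pos, u, w, r_b, theta0) {
  u <- .unit(u)
  w <- .unit(w - sum(w * u) * u)
  h1 <- o_pos + r_b * (cos(theta0 / 2) * u + sin(theta0 / 2) * w)
  h2 <- o_pos + r_b * (cos(theta0 / 2) * u - sin(theta0 / 2) * w)
  rbind(h1, h2)
}

#' Generate a single frame with a planted hydrogen-bond motif
#'
#' Geometry is exact: the dimer realises the requested `(r_oh, alpha)` to
#' machine precision, the pentamer and lattice place donated hydrogens on
#' the O-O axes (inclination angle 0), and the monomer gas keeps every
#' intermolecular O..H separation above 0.35 nm.
#'
#' @param spec a [motif_spec()].
#' @param seed integer seed (used for monomer-gas orientations).
#' @return an [hb_frame()].
#' @export
gen_planted_configuration <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "motif_spec"))
  r_b <- 0.09572
  theta0 <- 104.52 * pi / 180
  L <- spec$box_length
  ctr <- rep(L / 2, 3)
  xyz <- switch(spec$kind,
    dimer = {
      a <- spec$alpha * pi / 180
      disc <- spec$r_oh^2 - (r_b * sin(a))^2
      if (disc < 0)
        stop("impossible dimer geometry: r_oh too short for this alpha")
      d_oo <- r_b * cos(a) + sqrt(disc)
      o_d <- c(0, 0, 0)
      h1 <- c(r_b, 0, 0)
      h2 <- r_b * c(cos(theta0), 0, sin(theta0))
      o_a <- d_oo * c(cos(a), sin(a), 0)
      ha <- .acceptor_h(o_a, .unit(o_a), c(0, 0, 1), r_b, theta0)
      m <- rbind(o_d, h1, h2, o_a, ha)
      sweep(m, 2, ctr - colMeans(m[c(1, 4), ]), "+")
    },
    pentamer = {
      tdirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
      d <- spec$o_o
      rows <- list()
      # central molecule donates along tdirs 1-2
      rows[[1]] <- rbind(ctr, ctr + r_b * tdirs[1, ], ctr + r_b * tdirs[2, ])
      # acceptors on tdirs 1-2, hydrogens pointing outward
      for (k in 1:2) {
        o <- ctr + d * tdirs[k, ]
        rows[[k + 1]] <- rbind(o, .acceptor_h(o, tdirs[k, ], tdirs[k %% 4 + 2, ],
                                              r_b, theta0))
      }
      # donors on tdirs 3-4, one H on the axis toward the centre
      for (k in 3:4) {
        o <- ctr + d * tdirs[k, ]
        w <- .unit(tdirs[(k %% 4) + 1, ] - sum(tdirs[(k %% 4) + 1, ] * tdirs[k, ]) * tdirs[k, ])
        h1 <- o - r_b * tdirs[k, ]
        h2 <- o + r_b * (cos(theta0) * (-tdirs[k, ]) + sin(theta0) * w)
        rows[[k + 1]] <- rbind(o, h1, h2)
      }
      do.call(rbind, rows)
    },
    lattice = {
      a_cell <- 4 * spec$o_o / sqrt(3)
      nc <- spec$count
      fcc <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
      donA <- rbind(c(1, 1, 1), c(1, -1, -1)) / sqrt(3)   # A-sublattice donations
      donB <- rbind(c(1, -1, 1), c(1, 1, -1)) / sqrt(3)   # B-sublattice donations
      rows <- list()
      idx <- 1L
      for (ix in seq_len(nc) - 1) for (iy in seq_len(nc) - 1) for (iz in seq_len(nc) - 1) {
        for (b in 1:4) {
          oA <- (c(ix, iy, iz) + fcc[b, ]) * a_cell
          rows[[idx]] <- rbind(oA, oA + r_b * donA[1, ], oA + r_b * donA[2, ]); idx <- idx + 1L
          oB <- oA + a_cell / 4
          rows[[idx]] <- rbind(oB, oB + r_b * donB[1, ], oB + r_b * donB[2, ]); idx <- idx + 1L
        }
      }
      do.call(rbind, rows)
    },
    monomer_gas = {
      n_side <- ceiling(spec$count^(1 / 3))
      grid <- as.matrix(expand.grid(x = seq_len(n_side), y = seq_len(n_side),
                                    z = seq_len(n_side))) - 0.5
      grid <- grid[seq_len(spec$count), , drop = FALSE] * spec$spacing
      with_seed(seed, {
        rows <- lapply(seq_len(spec$count), function(i) {
          o <- grid[i, ]
          u <- .unit(rnorm(3))
          w <- rnorm(3)
          hh <- .acceptor_h(o, u, w, r_b, theta0)
          rbind(o, hh)
        })
        do.call(rbind, rows)
      })
    })
  hb_frame(xyz, L, time = 0)
}

#' Two-state Markov bond-state series with optional absorbing escape
#'
#' Each entity starts bonded and evolves by a discrete-time approximation of
#' a continuous-time Markov chain at resolution `dt`: bonded -> broken with
#' per-step probability `1 - exp(-k_break*dt)`; a broken entity leaves the
#' broken state with probability `1 - exp(-(k_reform + k_escape)*dt)` and
#' then re-binds or escapes with probability proportional to the rates
#' (competing risks); escape is absorbing.  The continuous survival of the
#' bonded state is analytically `exp(-k_break * t)` and, with no escape, the
#' endpoint (intermittent) correlator relaxes to the stationary probability
#' `k_reform / (k_break + k_reform)`.
#'
#' @param n_entities number of independent bond processes.
#' @param k_break,k_reform,k_escape rates in 1/fs (all >= 0).
#' @param dt time step (fs).
#' @param n_steps number of stored steps (>= 2), including t = 0.
#' @param seed integer seed; output is reproducible bit-for-bit.
#' @return object of class `bond_state_series`: logical `states` matrix
#'   (entities x steps, `TRUE` = bonded), `dt`, `rates`, `seed`.
#' @export
gen_markov_bond_states <- function(n_entities, k_break, k_reform = 0,
                                   k_escape = 0, dt = 1, n_steps, seed = 1) {
  stopifnot(n_entities >= 1, n_steps >= 2, dt > 0,
            k_break >= 0, k_reform >= 0, k_escape >= 0)
  if (dt * max(k_break, k_reform + k_escape) > 0.1)
    stop("time discretization too coarse: dt * rate exceeds 0.1; ",
         "reduce dt or the rates")
  p_break <- 1 - exp(-k_break * dt)
  k_out <- k_reform + k_escape
  p_leave <- 1 - exp(-k_out * dt)
  p_reform_branch <- if (k_out > 0) k_reform / k_out else 0
  states <- matrix(FALSE, nrow = n_entities, ncol = n_steps)
  with_seed(seed, {
    cur <- rep(1L, n_entities)  # 1 bonded, 0 broken, 2 escaped
    states[, 1] <- TRUE
    for (s in 2:n_steps) {
      u <- runif(n_entities)
      bonded <- cur == 1L
      broken <- cur == 0L
      cur[bonded & u < p_break] <- 0L
      leave <- broken & u < p_leave
      if (any(leave)) {
        u2 <- runif(n_entities)
        cur[leave & u2 < p_reform_branch] <- 1L
        cur[leave & u2 >= p_reform_branch] <- 2L
      }
      states[, s] <- cur == 1L
    }
  })
  structure(list(states = states, dt = dt,
                 rates = c(k_break = k_break, k_reform = k_reform,
                           k_escape = k_escape),
                 n_entities = as.integer(n_entities), seed = seed),
            class = "bond_state_series")
}

#' @export
print.bond_state_series <- function(x, ...) {
  cat(sprintf(
    "<bond_state_series> %d entities x %d steps, dt = %g fs (k_break=%g, k_reform=%g, k_escape=%g /fs)\n",
    nrow(x$states), ncol(x$states), x$dt,
    x$rates["k_break"], x$rates["k_reform"], x$rates["k_escape"]))
  invisible(x)
}

#' Toy trajectory: jittered copies of a planted motif
#'
#' Replicates the planted frame `n_frames` times, translating each molecule
#' rigidly by an independent Gaussian displacement per frame.  If
#' `separate_at` is set, every even-indexed molecule (the dimer acceptor in
#' particular) is additionally displaced by half a box edge from the first
#' frame at or after that time onward - a deterministic bond-breaking event.
#'
#' @param spec a [motif_spec()].
#' @param jitter_sigma per-component Gaussian displacement (nm).
#' @param separate_at time (fs) of the breaking event, or `NULL`.
#' @param n_frames number of frames (>= 2).
#' @param dt frame spacing (fs).
#' @param seed integer seed.
#' @return an [hb_trajectory()].
#' @export
gen_toy_trajectory <- function(spec, jitter_sigma = 0, separate_at = NULL,
                               n_frames = 10, dt = 1, seed = 1) {
  stopifnot(n_frames >= 2, dt > 0, jitter_sigma >= 0)
  base <- gen_planted_configuration(spec, seed = seed)
  n_mol <- base$n_mol
  off <- c(0, 0, base$box_length / 2)
  frames <- with_seed(seed, lapply(seq_len(n_frames), function(k) {
    xyz <- base$xyz
    if (jitter_sigma > 0) {
      shift <- matrix(rnorm(3 * n_mol, sd = jitter_sigma), ncol = 3)
      xyz <- xyz + shift[rep(seq_len(n_mol), each = 3), ]
    }
    t_k <- (k - 1) * dt
    if (!is.null(separate_at) && t_k >= separate_at && n_mol >= 2) {
      movers <- which(seq_len(n_mol) %% 2 == 0)
      rows <- as.vector(vapply(movers, function(m) (3 * m - 2):(3 * m),
                               integer(3)))
      xyz[rows, ] <- sweep(xyz[rows, , drop = FALSE], 2, off, "+")
    }
    hb_frame(xyz, base$box_length, time = t_k)
  }))
  hb_trajectory(frames, metadata = list(motif = spec$kind, seed = seed))
}
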