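#' MD simulation configuration
#'
#' @param n_molecules number of water molecules (>= 2).
#' @param density system density (kg/L); fixes the cubic box length.
#' @param target_T target temperature (K).
#' @param dt integration step (fs).
#' @param store_stride store one frame every `store_stride` steps.
#' @param n_equil equilibration budget (steps).
#' @param n_prod production length (steps).
#' @param potential an [water_potential()]; Ewald parameters are finalized
#'   against the box at initialization.
#' @param seed integer seed for placement and velocities.
#' @return list of class `sim_config` with the derived `box_length` (nm).
#' @export
simulation_config <- function(n_molecules, density = 0.997, target_T = 300,
                              dt = 0.1, store_stride = 10L,
                              n_equil = 20000L, n_prod = 10000L,
                              potential = water_potential(), seed = 1) {
  stopifnot(n_molecules >= 2, density > 0, target_T > 0, dt > 0,
            store_stride >= 1)
  box <- water_box_length(n_molecules, density)
  if (box < 2 * potential$cutoff)
    stop(sprintf(
      "box (%.3f nm) must be at least twice the cutoff (%.3f nm); reduce the cutoff or the density",
      box, potential$cutoff))
  structure(list(n_molecules = as.integer(n_molecules), density = density,
                 target_T = target_T, dt = dt,
                 store_stride = as.integer(store_stride),
                 n_equil = as.integer(n_equil), n_prod = as.integer(n_prod),
                 box_length = box,
                 potential = finalize_potential(potential, box), seed = seed),
            class = "sim_config")
}

#' Cubic box edge for a given molecule count and density
#'
#' @param n_molecules molecule count.
#' @param density kg/L.
#' @return box edge in nm.
#' @export
water_box_length <- function(n_molecules, density) {
  mass_kg <- n_molecules * (.mass_O + 2 * .mass_H) * .amu_kg
  (mass_kg / (density * 1e3))^(1 / 3) * 1e9
}

.site_masses <- function(n_molecules) rep(c(.mass_O, .mass_H, .mass_H), n_molecules)

#' Initialize an MD state: random packing plus Boltzmann velocities
#'
#' Molecules with gas-phase internal geometry are placed at random positions
#' and orientations, rejecting placements with any O-O distance below
#' 0.24 nm; a short capped steepest-descent relaxation removes remaining hot
#' contacts.  Velocities are drawn from the Boltzmann distribution at
#' `target_T` with the net momentum removed and rescaled exactly to the
#' target kinetic temperature.
#'
#' @param config a [simulation_config()].
#' @return list of class `md_state`: `xyz`, `vel` (nm/ps), `box_length`,
#'   `potential`, `masses`, `time_fs`.
#' @export
init_configuration <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_molecules
  L <- config$box_length
  pot <- config$potential
  r_b <- pot$r_bond
  theta0 <- pot$theta0
  xyz <- with_seed(config$seed, {
    o_pos <- matrix(NA_real_, n, 3)
    placed <- 0L
    tries <- 0L
    while (placed < n) {
      tries <- tries + 1L
      if (tries > 2000L * n)
        stop("packing failure: could not place molecules at this density")
      cand <- runif(3, 0, L)
      if (placed > 0) {
        d <- minimum_image(sweep(o_pos[seq_len(placed), , drop = FALSE], 2, cand), L)
        if (min(sqrt(rowSums(d^2))) < 0.26) next
      }
      placed <- placed + 1L
      o_pos[placed, ] <- cand
    }
    rows <- lapply(seq_len(n), function(i) {
      u <- .unit(rnorm(3))
      w <- rnorm(3)
      rbind(o_pos[i, ], .acceptor_h(o_pos[i, ], u, w, r_b, theta0))
    })
    do.call(rbind, rows)
  })
  xyz <- md_relax_cpp(xyz, L, unclass(pot), 500L, 0.002)
  masses <- .site_masses(n)
  natoms <- 3L * n
  vel <- with_seed(config$seed + 1L, {
    v <- matrix(rnorm(natoms * 3), natoms, 3)
    v <- v / sqrt(masses)  # per-component sd ~ sqrt(kB T / m); T scale fixed below
    p <- colSums(v * masses)
    v <- sweep(v, 2, p / sum(masses))  # remove net momentum
    ke <- 0.5 * sum(masses * rowSums(v^2))
    T_now <- 2 * ke / (.kB * (3 * natoms - 3))
    v * sqrt(config$target_T / T_now)
  })
  structure(list(xyz = xyz, vel = vel, box_length = L, potential = pot,
                 masses = masses, n_molecules = n, time_fs = 0,
                 config = config),
            class = "md_state")
}

#' Forces and potential energy of an MD state
#'
#' Coulomb electrostatics by Ewald summation (shifted-force real-space part,
#' reciprocal sum, self and intramolecular-exclusion terms), Lennard-Jones
#' O-O with shifted-force truncation, harmonic intramolecular stretches and
#' bend.
#'
#' @param state an `md_state`.
#' @return list with `forces` (kJ/mol/nm), `e_pot` and energy components.
#' @export
compute_forces <- function(state) {
  stopifnot(inherits(state, "md_state"))
  md_forces_cpp(state$xyz, state$box_length, unclass(state$potential))
}

#' Advance an MD state by velocity-Verlet steps
#'
#' @param state an `md_state`.
#' @param n_steps number of steps.
#' @param dt step in fs (defaults to the configured step).
#' @return updated `md_state` with attributes from the run discarded.
#' @export
step_verlet <- function(state, n_steps = 1L, dt = NULL) {
  stopifnot(inherits(state, "md_state"))
  if (is.null(dt)) dt <- state$config$dt
  run <- md_run_cpp(state$xyz, state$vel, state$masses, state$box_length,
                    unclass(state$potential), as.integer(n_steps), dt * 1e-3,
                    as.integer(n_steps), -1, 0L)
  state$xyz <- run$xyz
  state$vel <- run$vel
  state$time_fs <- state$time_fs + n_steps * dt
  state
}

.kinetic_temperature <- function(state) {
  ke <- 0.5 * sum(state$masses * rowSums(state$vel^2))
  2 * ke / (.kB * (3 * nrow(state$vel) - 3))
}

#' Equilibrate by velocity rescaling until the temperature shows no trend
#'
#' Runs NVE chunks with periodic velocity rescaling to `target_T`, then
#' probes without rescaling: equilibration ends when a linear regression of
#' block-averaged temperature on time has a slope not significantly
#' different from zero (95% level) over 10 blocks.  Warns (and returns the
#' state) if the step budget is exhausted first.
#'
#' @param state an `md_state` from [init_configuration()].
#' @param config the [simulation_config()] (defaults to the state's own).
#' @return equilibrated `md_state` with attribute `equil_blocks` (block
#'   temperatures of the accepted probe).
#' @export
equilibrate <- function(state, config = state$config) {
  stopifnot(inherits(state, "md_state"))
  dt_ps <- config$dt * 1e-3
  chunk <- 200L
  n_probe <- 3000L
  probe_chunk <- 300L
  # main rescaling phase: most of the budget, so slow structural relaxation
  # (which keeps feeding potential energy into heat) is absorbed before the
  # trend is ever tested
  n_main <- max(config$n_equil %/% 2L, config$n_equil - 4L * n_probe)
  run <- md_run_cpp(state$xyz, state$vel, state$masses, state$box_length,
                    unclass(state$potential), n_main, dt_ps, chunk,
                    config$target_T, chunk)
  state$xyz <- run$xyz; state$vel <- run$vel
  state$time_fs <- state$time_fs + n_main * config$dt
  spent <- n_main
  repeat {
    # probe phase: pure NVE, block temperatures
    run <- md_run_cpp(state$xyz, state$vel, state$masses, state$box_length,
                      unclass(state$potential), n_probe, dt_ps, probe_chunk,
                      -1, 0L)
    blocks <- run$temperature[-1]
    trend <- lm(blocks ~ seq_along(blocks))
    p_slope <- summary(trend)$coefficients[2, 4]
    centered <- abs(mean(blocks) - config$target_T) < 5
    spent <- spent + n_probe
    if (p_slope > 0.05 && centered) {
      # accept the probe itself as the start of equilibrated dynamics
      state$xyz <- run$xyz; state$vel <- run$vel
      state$time_fs <- state$time_fs + n_probe * config$dt
      attr(state, "equil_blocks") <- blocks
      return(state)
    }
    if (spent >= config$n_equil) {
      state$xyz <- run$xyz; state$vel <- run$vel
      state$time_fs <- state$time_fs + n_probe * config$dt
      warning("equilibration budget exhausted before the temperature trend vanished")
      attr(state, "equil_blocks") <- blocks
      return(state)
    }
    # probe rejected: rescale away the residual drift and try again
    run <- md_run_cpp(run$xyz, run$vel, state$masses, state$box_length,
                      unclass(state$potential), n_probe, dt_ps, chunk,
                      config$target_T, chunk)
    state$xyz <- run$xyz; state$vel <- run$vel
    state$time_fs <- state$time_fs + 2L * n_probe * config$dt
    spent <- spent + n_probe
  }
}

#' NVE production run
#'
#' Integrates `n_prod` steps at fixed total energy, storing a frame every
#' `store_stride` steps, and reports the energy-stability ratio
#' `max |E(t) - E(0)| / |E(0)|` together with per-block temperatures.
#'
#' @param state an equilibrated `md_state`.
#' @param config the [simulation_config()] (defaults to the state's own).
#' @return list of class `md_production`: `trajectory` (an
#'   [hb_trajectory()]), `energy` (data.frame: time_fs, e_pot, e_kin, e_tot,
#'   temperature), `dE_over_E`, `block_T`, `momentum` (net, amu nm/ps).
#' @export
run_production <- function(state, config = state$config) {
  stopifnot(inherits(state, "md_state"))
  dt_ps <- config$dt * 1e-3
  run <- md_run_cpp(state$xyz, state$vel, state$masses, state$box_length,
                    unclass(state$potential), config$n_prod, dt_ps,
                    config$store_stride, -1, 0L)
  e_tot <- run$e_pot + run$e_kin
  dE <- max(abs(e_tot - e_tot[1])) / abs(e_tot[1])
  times <- state$time_fs + run$step * config$dt
  frames <- lapply(seq_along(run$step), function(k) {
    hb_frame(t(run$frames[, , k]), state$box_length, time = times[k])
  })
  traj <- hb_trajectory(frames, metadata = list(
    target_T = config$target_T, density = config$density, seed = config$seed))
  nb <- max(2L, min(10L, length(e_tot) %/% 10L))
  block_id <- cut(seq_along(run$temperature), nb, labels = FALSE)
  block_T <- tapply(run$temperature, block_id, mean)
  state$xyz <- run$xyz; state$vel <- run$vel
  state$time_fs <- state$time_fs + config$n_prod * config$dt
  momentum <- colSums(state$vel * state$masses)
  structure(list(trajectory = traj,
                 energy = data.frame(time_fs = times, e_pot = run$e_pot,
                                     e_kin = run$e_kin, e_tot = e_tot,
                                     temperature = run$temperature),
                 dE_over_E = dE, block_T = as.numeric(block_T),
                 momentum = momentum, final_state = state),
            class = "md_production")
}
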