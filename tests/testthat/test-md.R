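test_that("box length follows from count and density", {
  # 400 molecules at ambient density: edge close to 2.29 nm
  expect_equal(water_box_length(400, 0.997), 2.2894, tolerance = 1e-4)
  expect_equal(water_box_length(64, 0.997), 2.2894 * (64 / 400)^(1 / 3),
               tolerance = 1e-4)
})

test_that("initial state: packed without overlap, Boltzmann velocities, zero momentum", {
  cfg <- simulation_config(24, density = 0.8, target_T = 300, seed = 5,
                           potential = water_potential(cutoff = 0.45))
  st <- init_configuration(cfg)
  o <- st$xyz[seq(1, nrow(st$xyz), by = 3), ]
  for (i in seq_len(23)) {
    d <- minimum_image(sweep(o[(i + 1):24, , drop = FALSE], 2, o[i, ]),
                       st$box_length)
    expect_gt(min(sqrt(rowSums(d^2))), 0.2)  # relaxation may move them a little
  }
  expect_equal(hbkinetics:::.kinetic_temperature(st), 300, tolerance = 1e-9)
  p <- colSums(st$vel * st$masses)
  expect_equal(max(abs(p)), 0, tolerance = 1e-9)
  # deterministic under the seed
  st2 <- init_configuration(cfg)
  expect_identical(st$xyz, st2$xyz)
  expect_identical(st$vel, st2$vel)
})

test_that("Ewald electrostatics reproduce the rock-salt Madelung energy", {
  g <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * 0.5
  q <- (-1)^(rowSums(g / 0.5))
  ew <- hbkinetics:::ewald_energy_cpp(g, q, 1.0, alpha = 7, kmax = 18)
  madelung <- 1.74756459463318
  exact <- -4 * madelung * 138.935458 / 0.5
  expect_lt(abs(ew / exact - 1), 2e-6)
})

test_that("Ewald energy of a charge pair matches direct summation over periodic images", {
  ke <- 138.935458
  xyz <- rbind(c(0.1, 0.2, 0.3), c(0.4, 0.2, 0.3))
  q <- c(1, -1); L <- 1
  ew <- hbkinetics:::ewald_energy_cpp(xyz, q, L, alpha = 7, kmax = 18)
  # direct sum over cubes of images; conditionally convergent, so the
  # vacuum-boundary dipole term is added to the Ewald (tinfoil) result and
  # the cube sums are Richardson-extrapolated in 1/n^2
  M <- colSums(q * xyz)
  dip <- 2 * pi * ke * sum(M^2) / (3 * L^3)
  direct <- function(nmax) {
    sh <- as.matrix(expand.grid(-nmax:nmax, -nmax:nmax, -nmax:nmax))
    e <- 0
    for (i in 1:2) for (j in 1:2) {
      d <- sweep(sh, 2, xyz[j, ] - xyz[i, ], "-")
      r <- sqrt(rowSums(d^2))
      if (i == j) r <- r[r > 1e-9]
      e <- e + 0.5 * ke * q[i] * q[j] * sum(1 / r)
    }
    e
  }
  e1 <- direct(10); e2 <- direct(18)
  x1 <- 1 / 10^2; x2 <- 1 / 18^2
  extrap <- e2 + (e2 - e1) * x2 / (x1 - x2)
  expect_lt(abs((ew + dip) / extrap - 1), 1e-5)
})

test_that("forces are the exact gradient of the potential energy", {
  cfg <- simulation_config(6, density = 0.9, target_T = 300, seed = 9,
                           potential = water_potential(cutoff = 0.28))
  st <- init_configuration(cfg)
  ff <- compute_forces(st)
  expect_equal(colSums(ff$forces), c(0, 0, 0), tolerance = 1e-9)
  h <- 1e-6
  for (k in list(c(1, 1), c(4, 2), c(11, 3), c(18, 1))) {
    i <- k[1]; d <- k[2]
    xp <- st$xyz; xp[i, d] <- xp[i, d] + h
    xm <- st$xyz; xm[i, d] <- xm[i, d] - h
    ep <- hbkinetics:::md_forces_cpp(xp, st$box_length,
                                     unclass(st$potential))$e_pot
    em <- hbkinetics:::md_forces_cpp(xm, st$box_length,
                                     unclass(st$potential))$e_pot
    expect_equal(ff$forces[i, d], -(ep - em) / (2 * h), tolerance = 1e-4)
  }
})

test_that("short-range terms vanish continuously at the cutoff", {
  # an O-O pair crossing the cutoff: the change in energy and force across
  # the boundary must be of the order of the displacement, not of the raw
  # potential terms (shifted-force construction)
  pot2 <- hbkinetics:::finalize_potential(water_potential(cutoff = 0.5), 3)
  eps <- 1e-7
  base <- rbind(c(0, 0, 0), c(0.0957, 0, 0), c(-0.024, 0.0927, 0),
                c(0.5 - eps, 0, 0), c(0.5 - eps + 0.0957, 0, 0),
                c(0.5 - eps - 0.024, 0.0927, 0))
  outp <- base; outp[4:6, 1] <- outp[4:6, 1] + 2 * eps
  a <- hbkinetics:::md_forces_cpp(base, 3, unclass(pot2))
  b <- hbkinetics:::md_forces_cpp(outp, 3, unclass(pot2))
  # the O-O pair crosses the cutoff between the two evaluations: with the
  # shifted-force construction both energy and force are continuous there,
  # so the change is of the order of the 2e-7 nm displacement
  expect_lt(abs(a$e_pot - b$e_pot), 1e-5)
  expect_lt(max(abs(a$forces - b$forces)), 1e-3)
})

test_that("an isolated molecule at equilibrium geometry feels no intramolecular force", {
  pot <- hbkinetics:::finalize_potential(water_potential(cutoff = 0.5), 10)
  r_b <- pot$r_bond; th <- pot$theta0
  xyz <- rbind(c(5, 5, 5),
               c(5 + r_b, 5, 5),
               c(5 + r_b * cos(th), 5 + r_b * sin(th), 5))
  ff <- hbkinetics:::md_forces_cpp(xyz, 10, unclass(pot))
  expect_equal(ff$e_bond, 0, tolerance = 1e-12)
  expect_equal(ff$e_angle, 0, tolerance = 1e-12)
  # residual force is only the dipole coupling to the periodic images,
  # which falls off as the inverse cube of the box edge
  expect_lt(max(abs(ff$forces)), 0.02)
})

test_that("velocity Verlet is time-reversible and conserves energy on a vibrating molecule", {
  cfg <- simulation_config(2, density = 5e-4, target_T = 250, seed = 2,
                           potential = water_potential(cutoff = 0.6))
  st <- init_configuration(cfg)
  x0 <- st$xyz; v0 <- st$vel
  fwd <- step_verlet(st, n_steps = 100)
  back <- fwd
  back$vel <- -back$vel
  rev <- step_verlet(back, n_steps = 100)
  expect_equal(rev$xyz, x0, tolerance = 1e-8)
  expect_equal(-rev$vel, v0, tolerance = 1e-8)
  # energy over 10^4 steps: bounded fluctuation, no secular drift, and the
  # fluctuation amplitude scales as dt^2 (second-order symplectic scheme)
  run <- hbkinetics:::md_run_cpp(x0, v0, st$masses, st$box_length,
                                 unclass(st$potential), 10000L, 1e-4, 10L,
                                 -1, 0L)
  e <- run$e_pot + run$e_kin
  expect_lt(max(abs(e - e[1])) / abs(e[1]), 1e-4)
  drift <- abs(mean(tail(e, 100)) - mean(head(e, 100))) / abs(e[1])
  expect_lt(drift, 1e-5)
  run2 <- hbkinetics:::md_run_cpp(x0, v0, st$masses, st$box_length,
                                  unclass(st$potential), 20000L, 5e-5, 10L,
                                  -1, 0L)
  e2 <- run2$e_pot + run2$e_kin
  expect_lt(max(abs(e2 - e2[1])), max(abs(e - e[1])) / 2.5)
})

test_that("zero net force produces uniform straight-line motion", {
  # neutral sites beyond the short-range cutoff: forces vanish identically,
  # so a translating molecule moves in a straight line at constant speed
  pot <- water_potential(q_o = 0, q_h = 0, cutoff = 0.5)
  cfg <- simulation_config(2, density = 0.001, target_T = 10, seed = 4,
                           potential = pot)
  st <- init_configuration(cfg)
  st$xyz[1:3, ] <- sweep(st$xyz[1:3, ], 2, st$xyz[1, ] - c(0.5, 0.5, 0.5))
  st$xyz[4:6, ] <- sweep(st$xyz[4:6, ], 2, st$xyz[4, ] - c(2.4, 2.4, 2.4))
  st$vel <- matrix(0, nrow(st$vel), 3)
  st$vel[1:3, 1] <- 0.5   # nm/ps
  f0 <- compute_forces(st)
  expect_lt(max(abs(f0$forces)), 1e-9)
  adv <- step_verlet(st, n_steps = 50, dt = 0.1)
  expect_equal(adv$xyz[1:3, 1] - st$xyz[1:3, 1], rep(0.5 * 5e-3, 3),
               tolerance = 1e-9)
})
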