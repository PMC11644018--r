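test_that("Markov generator honours its rate semantics", {
  # no breaking: everything stays bonded
  bs <- gen_markov_bond_states(20, k_break = 0, k_reform = 0, dt = 1,
                               n_steps = 50, seed = 1)
  expect_true(all(bs$states))

  # per-step break frequency among bonded entities ~ 1 - exp(-k dt)
  bs <- gen_markov_bond_states(3000, k_break = 0.02, k_reform = 0, dt = 1,
                               n_steps = 60, seed = 2)
  s <- bs$states
  bonded_before <- s[, -ncol(s)]
  broke <- bonded_before & !s[, -1]
  p_hat <- sum(broke) / sum(bonded_before)
  p <- 1 - exp(-0.02)
  n <- sum(bonded_before)
  expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / n))

  # reproducible bit-for-bit under the seed
  bs2 <- gen_markov_bond_states(3000, k_break = 0.02, k_reform = 0, dt = 1,
                                n_steps = 60, seed = 2)
  expect_identical(bs$states, bs2$states)

  # too-coarse discretization is rejected
  expect_error(gen_markov_bond_states(5, k_break = 0.2, dt = 1, n_steps = 5),
               "too coarse")
})

test_that("escape is absorbing and suppresses rebinding", {
  bs <- gen_markov_bond_states(500, k_break = 0.05, k_reform = 0.05,
                               k_escape = 0.05, dt = 1, n_steps = 300,
                               seed = 3)
  s <- bs$states
  # find entities that ever leave the bonded state for good: after the last
  # TRUE there must be no later TRUE (trivially), but more sharply, the
  # bonded fraction must reach (near) zero as everything eventually escapes
  expect_lt(mean(s[, ncol(s)]), 0.05)
  # once an entity has escaped it never re-binds: reconstruct escape as
  # "broken forever after"; any TRUE after a 50-step all-FALSE stretch would
  # be overwhelmingly unlikely unless escape were leaky.  Check directly
  # that no entity re-binds after 100 consecutive broken steps.
  run_broken <- function(row) {
    r <- rle(row)
    idx <- which(!r$values & r$lengths >= 100)
    if (!length(idx)) return(TRUE)
    last_rebind <- max(cumsum(r$lengths)[idx[1]] < which(row))
    !any(which(row) > sum(r$lengths[seq_len(idx[1])]))
  }
  expect_true(all(apply(s, 1, run_broken)))
})

test_that("continuous survival matches the event-driven (Gillespie) oracle", {
  k <- 0.01
  bs <- gen_markov_bond_states(10000, k_break = k, k_reform = 0, dt = 1,
                               n_steps = 101, seed = 4)
  frac_gen <- mean(apply(bs$states[, 1:101], 1, all))
  frac_ev <- gillespie_survival_fraction(10000, k, 100, seed = 5)
  p <- exp(-1)
  band <- 3 * sqrt(p * (1 - p) / 10000)
  expect_lt(abs(frac_gen - p), band)
  expect_lt(abs(frac_ev - p), band)
  expect_lt(abs(frac_gen - frac_ev), sqrt(2) * band)
})

test_that("planted dimer realises the requested geometry exactly", {
  for (case in list(c(0.18, 5), c(0.22, 25), c(0.249, 1))) {
    f <- gen_planted_configuration(motif_spec("dimer", r_oh = case[1],
                                              alpha = case[2]))
    g <- hb_geometry(f, 1, 1, 2)
    expect_equal(unname(g["r_oh"]), case[1], tolerance = 1e-9)
    expect_equal(unname(g["alpha"]), case[2], tolerance = 1e-6)
  }
  expect_error(gen_planted_configuration(
    motif_spec("dimer", r_oh = 0.01, alpha = 60)), "impossible")
})

test_that("planted pentamer, lattice and monomer gas have the advertised bonds", {
  fp <- gen_planted_configuration(motif_spec("pentamer"))
  bp <- detect_bonds(fp)
  counts <- nhb_counts(bp, 5)
  expect_equal(counts$counts, c(4, 1, 1, 1, 1))
  expect_equal(counts$mean_nhb, 1.6)

  fl <- gen_planted_configuration(motif_spec("lattice", count = 2))
  bl <- detect_bonds(fl)
  expect_equal(fl$n_mol, 64L)
  expect_equal(nrow(bl), 128)          # every molecule donates 2, accepts 2
  expect_true(all(nhb_counts(bl, 64)$counts == 4))

  fm <- gen_planted_configuration(motif_spec("monomer_gas", count = 50))
  bm <- detect_bonds(fm)
  expect_equal(nrow(bm), 0)
  expect_equal(detect_monomers(fm, bm), 1:50)
  # all intermolecular O..H separations really exceed 0.35 nm
  o <- fm$xyz[seq(1, 150, by = 3), ]
  h <- fm$xyz[-seq(1, 150, by = 3), ]
  mol_of_h <- rep(1:50, each = 2)
  for (i in 1:50) {
    d <- sweep(h[mol_of_h != i, ], 2, o[i, ])
    d <- minimum_image(d, fm$box_length)
    expect_gt(min(sqrt(rowSums(d^2))), 0.35)
  }
})

test_that("toy trajectory: deterministic separation produces a step correlator", {
  tr <- gen_toy_trajectory(motif_spec("dimer"), jitter_sigma = 0,
                           separate_at = 5, n_frames = 10, dt = 1, seed = 1)
  series <- detect_bonds_trajectory(tr)
  # bonded frames 1..5 (t = 0..4), broken from t = 5 on
  expect_equal(unname(series$pair_states[1, ]),
               c(rep(TRUE, 5), rep(FALSE, 5)))
  hc <- continuous_correlation(series, origins = 1, max_lag = 9)
  expect_equal(hc$value, c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0))
  # no separation, no jitter: flat correlator
  tr0 <- gen_toy_trajectory(motif_spec("dimer"), jitter_sigma = 0,
                            n_frames = 6, dt = 1, seed = 1)
  s0 <- detect_bonds_trajectory(tr0)
  h0 <- continuous_correlation(s0, origins = 1, max_lag = 5)
  expect_equal(h0$value, rep(1, 6))
})

test_that("jittered borderline dimer matches a per-frame brute-force re-check", {
  spec <- motif_spec("dimer", r_oh = 0.245, alpha = 25)
  tr <- gen_toy_trajectory(spec, jitter_sigma = 0.02, n_frames = 15, dt = 1,
                           seed = 8)
  crit <- hb_criteria()
  pot <- water_potential()
  series <- detect_bonds_trajectory(tr, crit, pot)
  for (k in seq_len(15)) {
    oracle <- oracle_detect(tr$frames[[k]], crit, pot)
    got <- series$bonds[[k]]
    expect_equal(nrow(got), nrow(oracle), info = paste("frame", k))
  }
})
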