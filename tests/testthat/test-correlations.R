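test_that("origin sampling is uniform over the censoring-free window", {
  expect_equal(sample_origins(101, 100, 1), 1L)
  o <- sample_origins(500, 100, 50, seed = 4)
  expect_equal(anyDuplicated(o), 0)
  expect_true(all(o >= 1 & o <= 400))
  expect_identical(o, sample_origins(500, 100, 50, seed = 4))
  expect_error(sample_origins(100, 100, 1), "exceed")
  expect_error(sample_origins(120, 100, 50), "origins")
})

test_that("hand-evaluated correlators: persistence, endpoint returns, monomers", {
  # one pair bonded at frames 1..5 of 10
  m <- matrix(FALSE, 1, 10); m[1, 1:5] <- TRUE
  hc <- continuous_correlation(m, origins = 1, max_lag = 9)
  expect_equal(hc$value, c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0))
  # pair bonded at frames 1 and 8 only: intermittent sees the return
  m2 <- matrix(FALSE, 1, 10); m2[1, c(1, 8)] <- TRUE
  hi <- intermittent_correlation(m2, origins = 1, max_lag = 9)
  expect_equal(hi$value, c(1, 0, 0, 0, 0, 0, 0, 1, 0, 0))
  hc2 <- continuous_correlation(m2, origins = 1, max_lag = 9)
  expect_equal(hc2$value, c(1, rep(0, 9)))
  # molecule non-bonded at frames 1..3, bonded at 4
  m3 <- matrix(TRUE, 1, 6); m3[1, 4:6] <- FALSE
  mo <- monomer_correlation(m3, origins = 1, max_lag = 5)
  expect_equal(mo$value, c(1, 1, 1, 0, 0, 0))
  # no active entity at the origin is an error
  m4 <- matrix(FALSE, 2, 5)
  expect_error(continuous_correlation(m4, 1, 3), "undefined")
})

test_that("pooled estimator reduces to the single-origin estimator", {
  bs <- gen_markov_bond_states(50, k_break = 0.05, k_reform = 0.05, dt = 1,
                               n_steps = 120, seed = 6)
  one <- intermittent_correlation(bs, origins = 17, max_lag = 40)
  # pooling a single origin is the same computation
  expect_equal(one$n_origins, 1)
  expect_equal(one$denominator, sum(bs$states[, 17]))
  many <- intermittent_correlation(bs, origins = c(17, 41), max_lag = 40)
  expect_gte(many$denominator, one$denominator)
})

test_that("correlators live in [0,1], start at 1, and survival modes never increase", {
  for (seed in 1:6) {
    set.seed(seed)
    bs <- gen_markov_bond_states(80, k_break = runif(1, 0.005, 0.05),
                                 k_reform = runif(1, 0, 0.05),
                                 k_escape = runif(1, 0, 0.02),
                                 dt = 1, n_steps = 200, seed = seed)
    o <- sample_origins(200, 80, 10, seed = seed)
    hc <- continuous_correlation(bs, o, 80)
    hi <- intermittent_correlation(bs, o, 80)
    for (v in list(hc$value, hi$value)) {
      expect_true(all(v >= 0 & v <= 1))
      expect_equal(v[1], 1)
    }
    expect_true(all(diff(hc$value) <= 1e-12))
    expect_true(all(hi$value - hc$value >= -1e-12))
  }
})

test_that("Markov estimates converge to the analytic forms", {
  # continuous survival of the bonded state
  bs <- gen_markov_bond_states(4000, k_break = 0.01, k_reform = 0.1, dt = 1,
                               n_steps = 800, seed = 11)
  o <- sample_origins(800, 400, 40, seed = 2)
  hc <- continuous_correlation(bs, o, 400)
  p <- markov_correlation_theory(hc$lag, 0.01, mode = "continuous")
  band <- 3 * sqrt(pmax(p * (1 - p), 1e-6) / 4000)
  expect_true(all(abs(hc$value - p) <= band + 0.005))
  # intermittent correlator against the 2x2 rate-matrix exponential
  kb <- 0.004; kr <- 0.006
  bs2 <- gen_markov_bond_states(4000, k_break = kb, k_reform = kr, dt = 1,
                                n_steps = 1500, seed = 12)
  o2 <- sample_origins(1500, 700, 40, seed = 3)
  hi <- intermittent_correlation(bs2, o2, 700)
  Q <- matrix(c(-kb, kb, kr, -kr), 2, 2, byrow = TRUE)
  t_chk <- c(0, 50, 150, 400, 700)
  for (tc in t_chk) {
    Pt <- as.matrix(Matrix::expm(Q * tc))
    theo <- Pt[1, 1]
    expect_lt(abs(hi$value[tc + 1] - theo),
              3 * sqrt(theo * (1 - theo) / 4000) + 0.01)
    # and the closed form used elsewhere agrees with the matrix exponential
    expect_equal(theo, markov_correlation_theory(tc, kb, kr, "intermittent"),
                 tolerance = 1e-10)
  }
  # inverted series: monomer survival matches the same exponential law
  bs3 <- gen_markov_bond_states(3000, k_break = 0.02, k_reform = 0, dt = 1,
                                n_steps = 300, seed = 13)
  m_nb <- bs3$states        # read the persistent state as "non-bonded"
  attr(m_nb, "dt") <- 1
  mo <- monomer_correlation(m_nb, sample_origins(300, 100, 20, seed = 5), 100)
  pm <- exp(-0.02 * mo$lag)
  expect_true(all(abs(mo$value - pm) <=
                    3 * sqrt(pmax(pm * (1 - pm), 1e-6) / 3000) + 0.005))
})
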