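test_that("pair interaction energy is symmetric, decays, and matches a site-loop oracle", {
  pot <- water_potential()
  fr <- random_frame(6, box_length = 8, seed = 3, min_oo = 2.5)
  # far-apart molecules interact weakly
  expect_lt(abs(pair_interaction_energy(fr, 1, 2, pot)), 0.5)
  # symmetry and oracle agreement on a dense frame
  fd <- random_frame(5, box_length = 0.8, seed = 7)
  for (pr in list(c(1, 2), c(2, 5), c(3, 4))) {
    e <- pair_interaction_energy(fd, pr[1], pr[2], pot)
    expect_identical(e, pair_interaction_energy(fd, pr[2], pr[1], pot))
    expect_equal(e, oracle_pair_energy(fd, pr[1], pr[2], pot),
                 tolerance = 1e-10)
  }
})

test_that("bond geometry: collinear arrangements, planted angles, and a second-formula oracle", {
  # H exactly on the O-O axis: alpha = 0
  xyz <- rbind(c(0, 0, 0), c(0.0957, 0, 0), c(-0.024, 0.0927, 0),
               c(0.28, 0, 0), c(0.33, 0.08, 0), c(0.33, -0.08, 0))
  f <- hb_frame(xyz, 3)
  g <- hb_geometry(f, 1, 1, 2)
  expect_equal(unname(g["alpha"]), 0, tolerance = 1e-9)
  expect_equal(unname(g["r_oh"]), 0.28 - 0.0957, tolerance = 1e-12)
  # planted dimer angle comes back exactly
  fd <- gen_planted_configuration(motif_spec("dimer", r_oh = 0.2, alpha = 25))
  expect_equal(unname(hb_geometry(fd, 1, 1, 2)["alpha"]), 25,
               tolerance = 1e-6)
  # dot-product formula agrees with the law-of-cosines route on random pairs
  fr <- random_frame(8, box_length = 1.0, seed = 9)
  for (k in 1:10) {
    don <- sample(8, 1); acc <- sample(setdiff(1:8, don), 1)
    h <- sample(2, 1)
    a1 <- unname(hb_geometry(fr, don, h, acc)["alpha"])
    a2 <- oracle_alpha_law_of_cosines(fr, don, h, acc)
    expect_equal(a1, a2, tolerance = 1e-8)
  }
})

test_that("each criterion acts as a strict inequality at its threshold", {
  pot <- water_potential()
  # distance threshold: planted exactly at r_max is out, just inside is in
  f_at <- gen_planted_configuration(motif_spec("dimer", r_oh = 0.25, alpha = 5))
  f_in <- gen_planted_configuration(motif_spec("dimer", r_oh = 0.2499, alpha = 5))
  expect_equal(nrow(detect_bonds(f_at, hb_criteria(), pot)), 0)
  expect_equal(nrow(detect_bonds(f_in, hb_criteria(), pot)), 1)
  # angle threshold, default and more-linear variant
  # r_oh chosen so the pair energy stays below -8 kJ/mol on both sides of
  # the 30-degree cutoff: the flip is attributable to the angle alone
  f29 <- gen_planted_configuration(motif_spec("dimer", r_oh = 0.23, alpha = 29.5))
  f30 <- gen_planted_configuration(motif_spec("dimer", r_oh = 0.23, alpha = 30))
  f31 <- gen_planted_configuration(motif_spec("dimer", r_oh = 0.23, alpha = 31))
  expect_equal(nrow(detect_bonds(f29, hb_criteria(), pot)), 1)
  expect_equal(nrow(detect_bonds(f30, hb_criteria(), pot)), 0)
  expect_equal(nrow(detect_bonds(f31, hb_criteria(), pot)), 0)
  f19 <- gen_planted_configuration(motif_spec("dimer", r_oh = 0.2, alpha = 19.9))
  f20 <- gen_planted_configuration(motif_spec("dimer", r_oh = 0.2, alpha = 20))
  crit20 <- hb_criteria(alpha_max = 20)
  expect_equal(nrow(detect_bonds(f19, crit20, pot)), 1)
  expect_equal(nrow(detect_bonds(f20, crit20, pot)), 0)
  # energy threshold: pin the cutoff at the dimer's own pair energy
  fd <- gen_planted_configuration(motif_spec("dimer", r_oh = 0.2, alpha = 10))
  e_star <- pair_interaction_energy(fd, 1, 2, pot)
  expect_equal(nrow(detect_bonds(fd, hb_criteria(e_max = e_star), pot)), 0)
  expect_equal(nrow(detect_bonds(fd, hb_criteria(e_max = e_star + 0.01), pot)), 1)
  expect_equal(nrow(detect_bonds(fd, hb_criteria(e_max = e_star - 0.01), pot)), 0)
})

test_that("prefiltered detector equals the exhaustive all-triples oracle on random frames", {
  crit <- hb_criteria()
  pot <- water_potential()
  for (seed in 1:8) {
    fr <- random_frame(12, box_length = 1.0, seed = seed)
    got <- detect_bonds(fr, crit, pot)
    plain <- detect_bonds(fr, crit, pot, prefilter = FALSE)
    oracle <- oracle_detect(fr, crit, pot)
    key <- function(m) unname(sort(apply(unname(as.matrix(m)), 1, paste, collapse = "/")))
    expect_equal(key(as.matrix(got[, 1:3])), key(as.matrix(plain[, 1:3])))
    expect_equal(key(as.matrix(got[, 1:3])), key(oracle))
  }
})

test_that("tightening any criterion yields a nested bond set", {
  pot <- water_potential()
  base <- hb_criteria()
  key <- function(b) unname(apply(unname(as.matrix(b[, 1:3])), 1, paste, collapse = "/"))
  for (seed in 1:6) {
    fr <- random_frame(14, box_length = 1.0, seed = 100 + seed)
    b0 <- key(detect_bonds(fr, base, pot))
    for (tight in list(hb_criteria(r_max = 0.22),
                       hb_criteria(alpha_max = 20),
                       hb_criteria(e_max = -12))) {
      expect_true(all(key(detect_bonds(fr, tight, pot)) %in% b0))
    }
  }
})

test_that("monomers and bonded molecules partition every frame", {
  pot <- water_potential()
  fr <- random_frame(15, box_length = 1.1, seed = 21)
  b <- detect_bonds(fr, hb_criteria(), pot)
  mono <- detect_monomers(fr, b)
  bonded <- unique(c(b$donor, b$acceptor))
  expect_length(intersect(mono, bonded), 0)
  expect_setequal(c(mono, bonded), 1:15)
  # bonded dimer plus one far molecule: exactly the far one is a monomer
  fd <- gen_planted_configuration(motif_spec("dimer"))
  far <- rbind(c(0.2, 0.2, 2.0), c(0.29, 0.2, 2.0), c(0.17, 0.29, 2.0))
  f3 <- hb_frame(rbind(fd$xyz, far), fd$box_length)
  b3 <- detect_bonds(f3, hb_criteria(), pot)
  expect_equal(detect_monomers(f3, b3), 3L)
})

test_that("bond counts obey the handshake identity", {
  fr <- random_frame(15, box_length = 1.0, seed = 33)
  b <- detect_bonds(fr)
  nh <- nhb_counts(b, 15)
  expect_equal(sum(nh$counts), 2 * nrow(b))
  expect_equal(nhb_counts(b[0, ], 15)$counts, rep(0L, 15))
})
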