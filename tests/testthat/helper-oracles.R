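# Independent brute-force oracles used across the suite.  These deliberately
# re-derive quantities by a different route than the package implementation.

# random dense-ish water frame: rejection-packed oxygens, random orientations
random_frame <- function(n_mol, box_length = 1.2, seed = 1, min_oo = 0.24) {
  set.seed(seed)
  r_b <- 0.09572
  theta0 <- 104.52 * pi / 180
  o_pos <- matrix(NA_real_, n_mol, 3)
  placed <- 0
  while (placed < n_mol) {
    cand <- runif(3, 0, box_length)
    if (placed > 0) {
      d <- o_pos[seq_len(placed), , drop = FALSE]
      d <- sweep(d, 2, cand)
      d <- d - box_length * round(d / box_length)
      if (min(sqrt(rowSums(d^2))) < min_oo) next
    }
    placed <- placed + 1
    o_pos[placed, ] <- cand
  }
  rows <- lapply(seq_len(n_mol), function(i) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    w <- rnorm(3); w <- w - sum(w * u) * u; w <- w / sqrt(sum(w^2))
    h1 <- o_pos[i, ] + r_b * (cos(theta0 / 2) * u + sin(theta0 / 2) * w)
    h2 <- o_pos[i, ] + r_b * (cos(theta0 / 2) * u - sin(theta0 / 2) * w)
    rbind(o_pos[i, ], h1, h2)
  })
  hb_frame(do.call(rbind, rows), box_length)
}

# minimum image by explicit loop subtraction (oracle for the vectorized one)
naive_min_image <- function(v, L) {
  vapply(v, function(x) {
    while (x > L / 2) x <- x - L
    while (x <= -L / 2) x <- x + L
    x
  }, numeric(1))
}

# pair energy by an independently coded double loop over the 9 site pairs
# plus the short-range terms, using naive_min_image
oracle_pair_energy <- function(frame, i, j, pot) {
  ke <- 138.935458
  q <- c(pot$q_o, pot$q_h, pot$q_h)
  ai <- frame$xyz[(3 * i - 2):(3 * i), ]
  aj <- frame$xyz[(3 * j - 2):(3 * j), ]
  e <- 0
  for (s1 in 1:3) for (s2 in 1:3) {
    d <- naive_min_image(ai[s1, ] - aj[s2, ], frame$box_length)
    r <- sqrt(sum(d^2))
    e <- e + ke * q[s1] * q[s2] / r
    if (xor(s1 == 1, s2 == 1)) e <- e + pot$c_ohrep / r^16
  }
  d <- naive_min_image(ai[1, ] - aj[1, ], frame$box_length)
  r <- sqrt(sum(d^2))
  e + 4 * pot$lj_eps * ((pot$lj_sigma / r)^12 - (pot$lj_sigma / r)^6)
}

# angle by law of cosines from the three side lengths (second formula);
# the acceptor image nearest the donor oxygen is fixed first so the three
# sides form a consistent triangle under periodic boundaries
oracle_alpha_law_of_cosines <- function(frame, donor, h_index, acceptor) {
  L <- frame$box_length
  o_d <- frame$xyz[3 * donor - 2, ]
  h <- frame$xyz[3 * donor - 2 + h_index, ]
  o_a_img <- o_d + naive_min_image(frame$xyz[3 * acceptor - 2, ] - o_d, L)
  a <- sqrt(sum((h - o_d)^2))              # donor OH
  b <- sqrt(sum((o_a_img - o_d)^2))        # O-O
  c_ <- sqrt(sum((o_a_img - h)^2))         # H..O in the same image
  acos((a^2 + b^2 - c_^2) / (2 * a * b)) * 180 / pi
}

# exhaustive all-triples bond detector, no prefilter, independent energy
oracle_detect <- function(frame, criteria, pot) {
  n <- frame$n_mol
  out <- list()
  for (don in seq_len(n)) for (acc in seq_len(n)) {
    if (don == acc) next
    for (h in 1:2) {
      o_a <- frame$xyz[3 * acc - 2, ]
      hp <- frame$xyz[3 * don - 2 + h, ]
      r_oh <- sqrt(sum(naive_min_image(o_a - hp, frame$box_length)^2))
      if (r_oh >= criteria$r_max) next
      alpha <- oracle_alpha_law_of_cosines(frame, don, h, acc)
      if (alpha >= criteria$alpha_max) next
      if (oracle_pair_energy(frame, don, acc, pot) >= criteria$e_max) next
      out[[length(out) + 1]] <- c(don, h, acc)
    }
  }
  if (length(out) == 0) return(matrix(integer(), 0, 3))
  do.call(rbind, out)
}

# connected components by breadth-first search over an edge list
oracle_components <- function(edges, n) {
  adj <- vector("list", n)
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; comp <- integer()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps[order(vapply(comps, min, numeric(1)))]
}

# event-driven (Gillespie-style) sampler of the continuous bonded-survival
# time for a single bond with break rate k
gillespie_survival_fraction <- function(n, k_break, t_check, seed) {
  set.seed(seed)
  mean(rexp(n, rate = k_break) > t_check)
}

# random bond table on n molecules (for graph oracles)
random_bond_table <- function(n, p_edge, seed) {
  set.seed(seed)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p_edge
  pairs <- pairs[keep, , drop = FALSE]
  data.frame(donor = pairs[, 1], h_index = 1L, acceptor = pairs[, 2],
             r_oh = 0.19, alpha = 5, e_pair = -10)
}
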