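test_that("reduced state spaces match their closed-form counts", {
  sp <- enumerate_states(".00.1", 6, 2)
  expect_equal(sp$n_states, 22L)               # 6+6+4+2+2+1 + DETACHED
  sp2 <- enumerate_states("0", 2, 1)
  expect_equal(sp2$n_states, 4L)               # (0,1),(0,0),(1,0),DETACHED
  # T = 1: no Edman cycles, prod_c (n_c(0)+1) + DETACHED
  for (code in c("010", "0011", ".0.1")) {
    n0 <- dye_counts_after(code, 2)[1, ]
    expect_equal(enumerate_states(code, 1, 2)$n_states,
                 prod(n0 + 1) + 1L)
  }
  set.seed(31)
  for (i in 1:10) {
    code <- random_code(6, 4, 2)
    Tn <- sample(1:6, 1)
    sp <- enumerate_states(code, Tn, 2)
    n <- dye_counts_after(code, 2)
    e_max <- min(nchar(code), Tn - 1L)
    expect_equal(sp$n_states,
                 sum(vapply(0:e_max, function(e) prod(n[e + 1, ] + 1),
                            numeric(1))) + 1L)
  }
})

test_that("initial distribution is binomial in the dud rate", {
  pp <- seq_params(m = 0.07, n_channels = 1, n_timesteps = 2)
  sp <- enumerate_states("0", 2, 1)
  pi0 <- initial_distribution(sp, pp)
  expect_equal(sum(pi0), 1)
  expect_equal(pi0[sp$estar == 0L & sp$ell[, 1] == 1L], 0.93)
  expect_equal(pi0[sp$estar == 0L & sp$ell[, 1] == 0L], 0.07)
  # m = 0: point mass on full counts
  sp2 <- enumerate_states("00", 3, 1)
  pi2 <- initial_distribution(sp2, seq_params(m = 0, n_channels = 1,
                                              n_timesteps = 3))
  expect_equal(pi2[sp2$estar == 0L & sp2$ell[, 1] == 2L], 1)
  # n = 2, m = 0.5 -> (1/4, 1/2, 1/4)
  pi3 <- initial_distribution(sp2, seq_params(m = 0.5, n_channels = 1,
                                              n_timesteps = 3))
  expect_equal(sort(pi3[pi3 > 0]), c(0.25, 0.25, 0.5))
})

test_that("transition factors carry the stated probabilities", {
  pp <- seq_params(n_channels = 1, n_timesteps = 3)
  sp <- enumerate_states("00", 3, 1)
  # dye loss: binomial thinning within a block
  D <- dye_loss_factor(sp, 1, 0.05)
  j <- sp$index_of(0L, 2L)
  expect_equal(D[sp$index_of(0L, 2L), j], 0.9025)
  expect_equal(D[sp$index_of(0L, 1L), j], 0.095)
  expect_equal(D[sp$index_of(0L, 0L), j], 0.0025)
  expect_equal(as.matrix(dye_loss_factor(sp, 1, 0)), diag(sp$n_states))
  D1 <- dye_loss_factor(sp, 1, 1)
  expect_equal(D1[sp$index_of(0L, 0L), sp$index_of(0L, 2L)], 1)
  # Edman: hypergeometric-style dye removal l/n
  E <- edman_factor(sp, 0.06)
  j2 <- sp$index_of(0L, 2L)
  expect_equal(E[j2, j2], 0.06)
  expect_equal(E[sp$index_of(1L, 1L), j2], 0.94)     # l/n = 1 forces removal
  j1 <- sp$index_of(0L, 1L)
  expect_equal(E[j1, j1], 0.06)
  expect_equal(E[sp$index_of(1L, 0L), j1], 0.47)     # removal, l/n = 1/2
  expect_equal(E[sp$index_of(1L, 1L), j1], 0.47)     # survivor keeps the dye
  # unlabeled removal leaves counts untouched
  spd <- enumerate_states(".0", 3, 1)
  Ed <- edman_factor(spd, 0.06)
  jd <- spd$index_of(0L, 1L)
  expect_equal(Ed[jd, jd], 0.06)
  expect_equal(Ed[spd$index_of(1L, 1L), jd], 0.94)
  # detachment
  expect_equal(as.matrix(detach_factor(sp, 0)), diag(sp$n_states))
  Dt <- detach_factor(sp, 0.05)
  expect_equal(Dt[j2, j2], 0.95)
  expect_equal(Dt[sp$detached, j2], 0.05)
  expect_equal(Dt[sp$detached, sp$detached], 1)
  Dt1 <- detach_factor(sp, 1)
  expect_equal(sum(Dt1[sp$detached, ]), sp$n_states)
})

test_that("every factor and their product are column-stochastic", {
  set.seed(32)
  for (i in 1:10) {
    code <- random_code(6, 4, 2)
    pp <- seq_params(n_channels = 2, n_timesteps = 5)
    m <- build_hmm(code, pp)
    for (f in m$factors) {
      expect_equal(max(abs(Matrix::colSums(f) - 1)), 0, tolerance = 1e-12)
    }
    expect_equal(max(abs(Matrix::colSums(m$trans) - 1)), 0, tolerance = 1e-12)
  }
})

test_that("composed factors equal an independently built dense matrix", {
  set.seed(33)
  for (i in 1:10) {
    code <- random_code(5, 3, 2)
    pp <- seq_params(n_channels = 2, n_timesteps = 4)
    m <- build_hmm(code, pp)
    dense <- dense_transition_oracle(m$space, pp)
    expect_lt(max(abs(dense - as.matrix(m$trans))), 1e-12)
  }
})

test_that("emission weights are products of per-channel Gaussian densities", {
  pp <- seq_params(n_channels = 1, n_timesteps = 2)
  sp <- enumerate_states("0", 2, 1)
  w <- emission_weights(sp, 1.0, pp)
  expect_equal(w[sp$estar == 0L & sp$ell[, 1] == 1L],
               dnorm(1, 1, sqrt(0.00667^2 + 0.16^2)))
  w0 <- emission_weights(sp, 0, pp)
  expect_equal(w0[sp$detached], dnorm(0, 0, 0.00667))
  expect_equal(w0[sp$detached], 59.82, tolerance = 1e-3)
  # two channels: product of the independent channel densities
  pp2 <- seq_params(n_channels = 2, n_timesteps = 2)
  sp2 <- enumerate_states("01", 2, 2)
  y <- c(0.9, 1.2)
  w2 <- emission_weights(sp2, y, pp2)
  i <- sp2$index_of(0L, c(1L, 1L))
  sd1 <- sqrt(0.00667^2 + 0.16^2)
  expect_equal(w2[i], dnorm(0.9, 1, sd1) * dnorm(1.2, 1, sd1))
  expect_error(emission_weights(sp2, c(NA, 1), pp2), "non-finite")
})

test_that("pruning keeps contiguous plausible count ranges and never empties", {
  pp <- seq_params(n_channels = 1, n_timesteps = 2)
  expect_equal(prune_ranges(2.0, pp, 5, 5)[[1]], 2:3)
  expect_equal(prune_ranges(2.0, pp, Inf, 5)[[1]], 0:5)
  for (l in 0:4) {
    expect_true(l %in% prune_ranges(l * 1.0, pp, 5, 4)[[1]])
  }
  # far-off observation: nearest-count fallback keeps one state
  rng <- prune_ranges(25, pp, 1e-6, 3)[[1]]
  expect_equal(rng, 3:3)
})

test_that("forward likelihood matches its two-state closed form at T = 1", {
  pp <- seq_params(n_channels = 1, n_timesteps = 1)
  m <- build_hmm("0", pp)
  lik <- forward_likelihood(m, matrix(1.0, 1, 1))
  closed <- 0.93 * dnorm(1, 1, sqrt(0.00667^2 + 0.16^2)) +
    0.07 * dnorm(1, 0, 0.00667)
  expect_equal(as.numeric(lik), closed, tolerance = 1e-12)
  expect_equal(as.numeric(lik), 2.3170, tolerance = 1e-4)
})

test_that("factored, dense and C++ forward passes agree; pruning is sound", {
  set.seed(34)
  for (i in 1:8) {
    code <- random_code(5, 3, 2)
    pp <- seq_params(n_channels = 2, n_timesteps = 5)
    m <- build_hmm(code, pp)
    tr <- simulate_dye_tracks(code, 1, pp)
    y <- matrix(fluorseq:::flatten_tracks(emit_raw_reads(tr, pp)),
                pp$n_timesteps, 2, byrow = TRUE)
    a <- as.numeric(fluorseq:::forward_likelihood_r(m, y))
    b <- as.numeric(fluorseq:::forward_likelihood_r(m, y, use_dense = TRUE))
    d <- as.numeric(forward_likelihood(m, y))
    expect_equal(a, b, tolerance = 1e-12)
    expect_equal(d, b, tolerance = 1e-12)
    # pruned C++ equals pruned R
    ap <- as.numeric(fluorseq:::forward_likelihood_r(m, y, cutoff = 5))
    dp <- as.numeric(forward_likelihood(m, y, cutoff = 5))
    expect_equal(dp, ap, tolerance = 1e-10)
  }
})

test_that("reduced-state likelihood equals the physical-state brute force", {
  set.seed(35)
  for (i in 1:10) {
    code <- random_code(5, 3, 2)
    pp <- seq_params(n_channels = 2, n_timesteps = sample(2:5, 1))
    m <- build_hmm(code, pp)
    for (j in 1:10) {
      tr <- simulate_dye_tracks(code, 1, pp)
      y <- matrix(fluorseq:::flatten_tracks(emit_raw_reads(tr, pp)),
                  pp$n_timesteps, 2, byrow = TRUE)
      a <- as.numeric(forward_likelihood(m, y))
      b <- physical_forward(code, pp, y)
      expect_lt(abs(a - b) / max(abs(b), 1e-300), 1e-9)
    }
  }
})

test_that("likelihood is invariant to trailing unlabeled residues", {
  pp <- seq_params(n_channels = 1, n_timesteps = 4)
  m1 <- build_hmm("0", pp)
  m2 <- build_hmm("0..", pp)
  set.seed(36)
  for (j in 1:10) {
    y <- matrix(rnorm(4, 0.3, 0.5), 4, 1)
    expect_equal(as.numeric(forward_likelihood(m1, y)),
                 as.numeric(forward_likelihood(m2, y)), tolerance = 1e-12)
  }
})

test_that("posterior scores follow Bayesian inversion and normalize", {
  expect_equal(as.numeric(posterior_scores(c(2, 1, 1))), c(0.5, 0.25, 0.25))
  expect_equal(as.numeric(posterior_scores(5)), 1)
  expect_equal(as.numeric(posterior_scores(c(1, 9), priors = c(0.9, 0.1))),
               c(0.5, 0.5))
  set.seed(37)
  for (i in 1:10) {
    lk <- runif(sample(2:8, 1))
    expect_equal(sum(posterior_scores(lk)), 1, tolerance = 1e-12)
  }
  expect_warning(p <- posterior_scores(c(0, 0)), "zero")
  expect_equal(as.numeric(p), c(0.5, 0.5))
  expect_true(attr(p, "degenerate"))
})

test_that("full Bayes classification recovers noiseless reads and breaks ties low", {
  pp <- seq_params(p = 0, m = 0, e = 0, d = 0, sigma = 0.05,
                   sigma_bg = 0.00667, n_channels = 1, n_timesteps = 3)
  ref <- merge_dye_seqs(c("0", "00"))
  models <- build_hmm_set(ref, pp)
  tr <- simulate_dye_tracks("0", 1, pp)
  y <- fluorseq:::flatten_tracks(emit_raw_reads(tr, pp))
  prm <- classify_bayes(y, models, cutoff = Inf)
  expect_equal(prm$dye_seq_id, 1L)
  expect_gt(prm$score, 0.999)
  # single-model reference: score exactly 1
  prm1 <- classify_bayes(y, models["1"], cutoff = Inf)
  expect_equal(prm1$score, 1)
})
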