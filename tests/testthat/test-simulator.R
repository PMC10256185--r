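test_that("deterministic simulator limits behave as the error model dictates", {
  p0 <- seq_params(p = 0, m = 0, e = 0, d = 0, n_channels = 1, n_timesteps = 3)
  tr <- simulate_dye_tracks("0", 4, p0)
  # Edman always succeeds: single labeled residue gone after the first cycle
  expect_true(all(tr[, 1, 1] == 1L))
  expect_true(all(tr[, 2:3, 1] == 0L))
  pd <- seq_params(p = 0, m = 0, e = 0, d = 1, n_channels = 1, n_timesteps = 3)
  tr <- simulate_dye_tracks("00", 4, pd)
  expect_true(all(tr[, 1, 1] == 2L))    # initial dyes logged before detachment
  expect_true(all(tr[, 2:3, 1] == 0L))
})

test_that("per-channel counts are non-increasing and bounded by n_c(0)", {
  set.seed(21)
  pp <- seq_params(n_channels = 2, n_timesteps = 6)
  for (code in c("01", "0.1.0", "110")) {
    tr <- simulate_dye_tracks(code, 200, pp)
    n0 <- dye_counts_after(code, 2)[1, ]
    for (ch in 1:2) {
      expect_true(all(tr[, , ch] <= n0[ch]))
      expect_true(all(apply(tr[, , ch], 1, function(z) all(diff(z) <= 0))))
    }
  }
})

test_that("dud and survival fractions match their closed forms", {
  set.seed(22)
  n <- 1e5
  pm <- seq_params(p = 0, m = 0.07, e = 0, d = 0, n_channels = 1,
                   n_timesteps = 1)
  tr <- simulate_dye_tracks("0", n, pm)
  dark <- mean(tr[, 1, 1] == 0L)
  expect_lt(abs(dark - 0.07), 3 * sqrt(0.07 * 0.93 / n))
  # single-dye marginal survival (1-m)(1-p)^t with Edman disabled
  pp <- seq_params(p = 0.05, m = 0.07, e = 1, d = 0, n_channels = 1,
                   n_timesteps = 5)
  tr <- simulate_dye_tracks("0", n, pp)
  for (t in 1:5) {
    expect_p <- 0.93 * 0.95^(t - 1)
    obs <- mean(tr[, t, 1] == 1L)
    expect_lt(abs(obs - expect_p), 3 * sqrt(expect_p * (1 - expect_p) / n))
  }
})

test_that("raw-read intensities follow the count-conditional Gaussian", {
  set.seed(23)
  pp <- seq_params(n_channels = 1, n_timesteps = 1)
  n <- 1e5
  # Lambda = 0: background only
  tr0 <- array(0L, dim = c(n, 1, 1))
  y0 <- emit_raw_reads(tr0, pp)
  expect_lt(abs(mean(y0)), 3 * 0.00667 / sqrt(n))
  expect_lt(abs(sd(y0) - 0.00667), 3 * 0.00667 / sqrt(2 * n))
  # Lambda = 1: variance adds per-fluorophore and background terms
  tr1 <- array(1L, dim = c(n, 1, 1))
  y1 <- emit_raw_reads(tr1, pp)
  sd_expect <- sqrt(0.00667^2 + 0.16^2)
  expect_lt(abs(mean(y1) - 1), 3 * sd_expect / sqrt(n))
  expect_lt(abs(sd(y1) - sd_expect), 3 * sd_expect / sqrt(2 * n))
  # degenerate noise limit: intensities collapse onto Lambda * mu
  ptiny <- seq_params(sigma = 1e-12, sigma_bg = 1e-12, n_channels = 1,
                      n_timesteps = 1)
  y <- emit_raw_reads(array(2L, dim = c(10, 1, 1)), ptiny)
  expect_equal(as.numeric(y), rep(2, 10), tolerance = 1e-9)
})

test_that("training sets deduplicate tracks and conserve counts", {
  pp0 <- seq_params(p = 0, m = 0, e = 0, d = 0, n_channels = 1,
                    n_timesteps = 3)
  ref1 <- merge_dye_seqs("0")
  tr <- generate_training_set(ref1, 5, pp0, seed = 1)
  expect_equal(nrow(tr$counts), 1L)
  expect_equal(tr$multiplicity, 5L)

  set.seed(24)
  ref <- tiny_reference(5, seed = 103)
  pp <- seq_params(n_channels = 3, n_timesteps = 5)
  train <- generate_training_set(ref, 200, pp, seed = 2)
  expect_equal(sum(train$votes$count) + train$n_discarded, 200L * nrow(ref))
  expect_equal(sum(train$multiplicity), sum(train$votes$count))
  expect_false(any(duplicated(apply(train$counts, 1, paste, collapse = ","))))
  expect_true(all(rowSums(train$counts) > 0))   # all-dark discarded
  # per-entry multiplicity equals the sum of its production counts
  by_entry <- tapply(train$votes$count, train$votes$entry, sum)
  expect_equal(as.integer(by_entry), train$multiplicity)
})

test_that("distinct dye sequences emitting the same track share one entry", {
  # with T = 1 and duds on, "00" can lose a dye and collide with "0"
  ref <- merge_dye_seqs(c("0", "00"))
  pp <- seq_params(p = 0, m = 0.3, e = 0, d = 0, n_channels = 1,
                   n_timesteps = 1)
  train <- generate_training_set(ref, 500, pp, seed = 3)
  one <- which(train$counts[, 1] == 1L)
  expect_length(one, 1L)
  v <- train$votes[train$votes$entry == one, ]
  expect_setequal(v$dye_seq_id, ref$dye_seq_id)
  expect_equal(sum(v$count), train$multiplicity[one])
})

test_that("test sets meet their quota with truth labels, excluding dark reads", {
  ref <- tiny_reference(3, seed = 104)
  pp <- seq_params(n_channels = 3, n_timesteps = 5)
  test <- generate_test_set(ref, 250, pp, seed = 4)
  expect_equal(nrow(test$y), 250L)
  expect_true(all(test$truth %in% ref$dye_seq_id))
  expect_true(all(mapply(function(id, pep) {
    pep %in% ref$peptides[[match(id, ref$dye_seq_id)]]
  }, test$truth, test$truth_peptide)))
  # rates zero: first-timestep counts equal n_c(0) exactly
  p0 <- seq_params(p = 0, m = 0, e = 0, d = 0, sigma = 1e-9,
                   sigma_bg = 1e-9, n_channels = 3, n_timesteps = 2)
  t0 <- generate_test_set(ref, 50, p0, seed = 5)
  for (r in 1:50) {
    n0 <- dye_counts_after(ref$code[match(t0$truth[r], ref$dye_seq_id)], 3)[1, ]
    expect_equal(round(t0$y[r, 1:3]), as.numeric(n0))
  }
  # impossible quota: every read dark
  pdark <- seq_params(m = 1, n_channels = 3, n_timesteps = 2)
  expect_error(generate_test_set(ref, 10, pdark, seed = 6, max_rounds = 3),
               "observable")
})

test_that("retained-read dark-at-t0 frequency matches the conditional binomial", {
  # dye seq "00", T = 1: retention requires >= 1 dye at t = 0, so
  # P(count = k | retained) is the zero-truncated binomial(2, 1 - m);
  # near-zero radiometry noise so intensities round back to exact counts
  pp <- seq_params(p = 0, m = 0.07, e = 0, d = 0, sigma = 1e-9,
                   sigma_bg = 1e-9, n_channels = 1, n_timesteps = 1)
  ref <- merge_dye_seqs("00")
  n <- 2e4
  test <- generate_test_set(ref, n, pp, seed = 7)
  counts <- round(test$y[, 1])
  p1 <- 2 * 0.93 * 0.07 / (1 - 0.07^2)
  obs <- mean(counts == 1)
  expect_lt(abs(obs - p1), 3 * sqrt(p1 * (1 - p1) / n))
  expect_true(all(counts >= 1))
})
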