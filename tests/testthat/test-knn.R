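make_small_index <- function(n_proteins = 5, n_per = 100, seed = 105) {
  ref <- tiny_reference(n_proteins, seed = seed)
  pp <- seq_params(n_channels = 3, n_timesteps = 6)
  train <- generate_training_set(ref, n_per, pp, seed = seed + 1)
  list(ref = ref, params = pp, train = train,
       index = build_knn_index(train, pp))
}

test_that("the index stores one point per unique track and finds itself", {
  fx <- make_small_index()
  expect_equal(nrow(fx$index$points), nrow(fx$train$counts))
  # query a stored vector: entry returned at distance zero
  for (e in c(1L, 7L, nrow(fx$index$points))) {
    nb <- query_neighbors(fx$index, fx$index$points[e, , drop = FALSE], 1)[[1]]
    expect_equal(nb$entry, e)
    expect_equal(nb$dist, 0)
  }
})

test_that("KD-tree kNN is exactly the linear-scan kNN", {
  fx <- make_small_index()
  set.seed(41)
  n_q <- 40
  q <- matrix(rnorm(n_q * ncol(fx$index$points), 0.5, 0.8), n_q)
  res <- query_neighbors(fx$index, q, 10)
  for (r in seq_len(n_q)) {
    oracle <- linear_knn(fx$index$points, q[r, ], 10)
    expect_equal(res[[r]]$entry, oracle$entry)
    expect_equal(res[[r]]$dist, oracle$dist, tolerance = 1e-12)
  }
  # k larger than the index returns everything, sorted
  all_nb <- query_neighbors(fx$index, q[1, , drop = FALSE],
                            nrow(fx$index$points) + 50)[[1]]
  expect_equal(nrow(all_nb), nrow(fx$index$points))
  expect_true(!is.unsorted(all_nb$dist))
})

test_that("vote weights follow the Gaussian kernel and proportional splits", {
  # hand-built two-entry training set: codes "0" and "00" collide at count 1
  ref <- merge_dye_seqs(c("0", "00"))
  pp <- seq_params(p = 0, m = 0.3, e = 0, d = 0, n_channels = 1,
                   n_timesteps = 1)
  train <- generate_training_set(ref, 400, pp, seed = 42)
  index <- build_knn_index(train, pp)
  e1 <- which(train$counts[, 1] == 1L)
  nb <- data.frame(entry = e1, dist = 0,
                   multiplicity = train$multiplicity[e1])
  w <- weight_votes(nb, index, sigma = 0.5)
  v <- train$votes[train$votes$entry == e1, ]
  expect_equal(sum(w), train$multiplicity[e1])      # delta = 0: kernel 1
  expect_equal(unname(w[as.character(v$dye_seq_id)]), v$count)
  # kernel value at delta = 0.5, sigma = 0.5
  nb2 <- data.frame(entry = e1, dist = 0.5,
                    multiplicity = train$multiplicity[e1])
  w2 <- weight_votes(nb2, index, sigma = 0.5)
  expect_equal(sum(w2), train$multiplicity[e1] * exp(-0.5), tolerance = 1e-12)
  expect_equal(as.numeric(w2 / w), rep(exp(-0.5), length(w)),
               tolerance = 1e-12)
})

test_that("kNN classification agrees with a full brute-force vote recount", {
  fx <- make_small_index(8, 150, seed = 106)
  test <- generate_test_set(fx$ref, 60, fx$params, seed = 43)
  prm <- classify_knn(fx$index, test, k = 10, sigma = 0.5)
  expect_true(all(prm$score > 0 & prm$score <= 1))
  for (r in seq_len(60)) {
    oracle_nb <- linear_knn(fx$index$points, test$y[r, ], 10)
    acc <- numeric(0)
    for (i in seq_along(oracle_nb$entry)) {
      e <- oracle_nb$entry[i]
      v <- fx$train$votes[fx$train$votes$entry == e, ]
      kern <- exp(-oracle_nb$dist[i]^2 / (2 * 0.25))
      for (q in seq_len(nrow(v))) {
        key <- as.character(v$dye_seq_id[q])
        acc[key] <- ifelse(is.na(acc[key]), 0, acc[key]) + v$count[q] * kern
      }
    }
    ids <- as.integer(names(acc))
    best <- ids[order(-acc, ids)][1]
    expect_equal(prm$dye_seq_id[r], best)
    expect_equal(prm$score[r], max(acc) / sum(acc), tolerance = 1e-9)
  }
})

test_that("scores are invariant to splitting merged entries into duplicates", {
  fx <- make_small_index(4, 80, seed = 107)
  # expand the deduplicated training set back into repeated single tracks
  tr <- fx$train
  rows <- rep(seq_len(nrow(tr$counts)), times = tr$multiplicity)
  expanded <- tr
  expanded$counts <- tr$counts[rows, , drop = FALSE]
  expanded$multiplicity <- rep(1L, length(rows))
  # rebuild votes: each duplicate carries one production count; assign
  # duplicates of an entry to its producing dye seqs in proportion
  votes <- do.call(rbind, lapply(seq_len(nrow(tr$counts)), function(e) {
    v <- tr$votes[tr$votes$entry == e, ]
    data.frame(dye_seq_id = rep(v$dye_seq_id, v$count), count = 1L)
  }))
  expanded$votes <- data.frame(entry = seq_along(rows),
                               dye_seq_id = votes$dye_seq_id,
                               count = votes$count)
  idx2 <- build_knn_index(expanded, fx$params)
  test <- generate_test_set(fx$ref, 30, fx$params, seed = 44)
  # k must count the same underlying mass: use all points in both indexes
  p1 <- classify_knn(fx$index, test, k = nrow(fx$index$points), sigma = 0.5)
  p2 <- classify_knn(idx2, test, k = nrow(idx2$points), sigma = 0.5)
  expect_equal(p1$dye_seq_id, p2$dye_seq_id)
  expect_equal(p1$score, p2$score, tolerance = 1e-9)
})
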