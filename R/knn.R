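#' Build a KD-tree kNN index over a deduplicated training set
#'
#' Training points are the flattened `T x C` dye-track count tensors scaled
#' by the per-channel mean intensity `mu_c` (so distances compare directly
#' with raw-read intensities). Each point carries its multiplicity and the
#' per-dye-sequence production counts from [generate_training_set()]. The
#' tree is static: it is never edited after construction.
#'
#' @param training A `dye_track_set`.
#' @param params A [seq_params()] object (supplies `mu`).
#' @return A `knn_index` object.
#' @export
build_knn_index <- function(training, params) {
  stopifnot(inherits(training, "dye_track_set"))
  if (nrow(training$counts) == 0L) stop("empty training set")
  Tn <- training$T; C <- training$C
  scale <- rep(params$mu, times = Tn)       # time-major columns
  pts <- sweep(matrix(as.double(training$counts), nrow(training$counts)),
               2, scale, `*`)
  ids <- sort(unique(training$votes$dye_seq_id))
  votes <- training$votes[order(training$votes$entry,
                                training$votes$dye_seq_id), , drop = FALSE]
  vote_ptr <- c(0L, cumsum(tabulate(votes$entry, nbins = nrow(pts))))
  obj <- list(points = pts, T = Tn, C = C,
              multiplicity = training$multiplicity,
              ids = ids,
              vote_ptr = vote_ptr,
              vote_id = match(votes$dye_seq_id, ids),
              vote_cnt = as.double(votes$count),
              votes = votes)
  obj$ptr <- kdtree_build(pts)
  class(obj) <- "knn_index"
  obj
}

# XPtr objects do not survive serialization; rebuild lazily when needed.
index_ptr <- function(index) {
  ptr <- index$ptr
  ok <- !is.null(ptr) &&
    tryCatch(kdtree_size(ptr) == nrow(index$points), error = function(e) FALSE)
  if (!ok) ptr <- kdtree_build(index$points)
  ptr
}

#' @export
print.knn_index <- function(x, ...) {
  cat(sprintf("<knn_index> %d unique tracks, dim %d (T=%d, C=%d), %d dye seqs\n",
              nrow(x$points), ncol(x$points), x$T, x$C, length(x$ids)))
  invisible(x)
}

#' Exact k nearest training tracks to raw reads
#'
#' @param index A [build_knn_index()] object.
#' @param reads Matrix `n x T*C` (time-major) or a `raw_read_set`.
#' @param k Number of neighbors.
#' @return List of data.frames (one per read) with columns `entry` (training
#'   entry index), `dist` (Euclidean distance), `multiplicity`; sorted by
#'   increasing distance, ties broken toward the lower entry index.
#' @export
query_neighbors <- function(index, reads, k) {
  y <- if (is.matrix(reads)) reads else reads$y
  if (ncol(y) != ncol(index$points)) stop("read shape does not match index")
  res <- kdtree_query(index_ptr(index), y, as.integer(k))
  lapply(seq_len(nrow(y)), function(r) {
    data.frame(entry = res$idx[r, ], dist = res$dist[r, ],
               multiplicity = index$multiplicity[res$idx[r, ]])
  })
}

#' Gaussian-kernel weighted voting over neighbors
#'
#' Each neighbor entry votes with weight `multiplicity * exp(-dist^2 /
#' (2 sigma^2))`, split across the dye sequences that produced the track
#' proportionally to their production counts.
#'
#' @param neighbors One element of [query_neighbors()] output.
#' @param index The [build_knn_index()] used for the query.
#' @param sigma Kernel bandwidth `sigma_kNN`.
#' @return Named numeric vector of vote weights per dye_seq_id, decreasing
#'   (ties toward lower id).
#' @export
weight_votes <- function(neighbors, index, sigma = 0.5) {
  stopifnot(nrow(neighbors) >= 1, sigma > 0)
  kern <- exp(-neighbors$dist^2 / (2 * sigma^2))
  acc <- numeric(length(index$ids))
  for (i in seq_len(nrow(neighbors))) {
    e <- neighbors$entry[i]
    vv <- (index$vote_ptr[e] + 1L):index$vote_ptr[e + 1L]
    acc[index$vote_id[vv]] <- acc[index$vote_id[vv]] +
      index$vote_cnt[vv] * kern[i]
  }
  touched <- sort(unique(index$vote_id[unlist(lapply(neighbors$entry,
    function(e) (index$vote_ptr[e] + 1L):index$vote_ptr[e + 1L]))]))
  w <- stats::setNames(acc[touched], index$ids[touched])
  w[order(-w, as.integer(names(w)))]
}

#' Classify raw reads with the kNN classifier
#'
#' Retrieves the `k` nearest deduplicated training tracks for each read,
#' weights votes with a Gaussian kernel, and reports the highest-weighted
#' dye sequence with score = its weight / total weight.
#'
#' @param index A [build_knn_index()] object.
#' @param reads Matrix `n x T*C` or a `raw_read_set`.
#' @param k Neighbor count (default 10, the standalone-kNN operating point).
#' @param sigma Kernel bandwidth (default 0.5).
#' @return Data.frame PRM table: `read`, `rank` (= 1), `dye_seq_id`, `score`.
#' @export
classify_knn <- function(index, reads, k = 10, sigma = 0.5) {
  y <- if (is.matrix(reads)) reads else reads$y
  if (ncol(y) != ncol(index$points)) stop("read shape does not match index")
  res <- kdtree_vote(index_ptr(index), y, as.integer(k), sigma,
                     index$vote_ptr, index$vote_id, index$vote_cnt,
                     length(index$ids), 1L)
  top <- res$ids[, 1]
  # an all-underflowed vote (total 0) falls back to the nearest entry's
  # dominant producer with score 1
  zero <- which(res$total <= 0 | top == 0L)
  score <- ifelse(res$total > 0, res$wts[, 1] / res$total, 1)
  if (length(zero)) {
    nb <- kdtree_query(index_ptr(index), y[zero, , drop = FALSE], 1L)
    for (i in seq_along(zero)) {
      e <- nb$idx[i, 1]
      vv <- (index$vote_ptr[e] + 1L):index$vote_ptr[e + 1L]
      best <- vv[order(-index$vote_cnt[vv], index$vote_id[vv])][1]
      top[zero[i]] <- index$vote_id[best]
      score[zero[i]] <- 1
    }
  }
  data.frame(read = seq_len(nrow(y)), rank = 1L,
             dye_seq_id = index$ids[top], score = score)
}
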