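#' Shortlist candidate dye sequences with the kNN pre-filter
#'
#' The two-stage classifier first reduces the reference, per read, to the
#' dye sequences that receive nonzero kNN vote weight, ranked by weight
#' (ties toward the lower id) and truncated to the top `h`. A read whose
#' votes all underflow falls back to the producers of its single nearest
#' training track.
#'
#' @param index A [build_knn_index()] object.
#' @param reads Matrix `n x T*C` or a `raw_read_set`.
#' @param k kNN neighbor count (default 10000, the hybrid operating point).
#' @param sigma Kernel bandwidth (default 0.5).
#' @param h Maximum shortlist length (default 1000).
#' @return List of integer vectors of dye_seq_ids, one per read.
#' @export
shortlist_candidates <- function(index, reads, k = 10000, sigma = 0.5,
                                 h = 1000) {
  stopifnot(h >= 1)
  y <- if (is.matrix(reads)) reads else reads$y
  if (ncol(y) != ncol(index$points)) stop("read shape does not match index")
  res <- kdtree_vote(index_ptr(index), y, as.integer(k), sigma,
                     index$vote_ptr, index$vote_id, index$vote_cnt,
                     length(index$ids), as.integer(min(h, length(index$ids))))
  out <- vector("list", nrow(y))
  for (r in seq_len(nrow(y))) {
    # the Gaussian kernel is strictly positive, so every dye sequence voted
    # for by a retrieved neighbor is a candidate even if its weight
    # underflows to zero in double precision
    sel <- res$ids[r, ]
    sel <- sel[sel > 0L]
    if (length(sel) == 0L) {
      nb <- kdtree_query(index_ptr(index), y[r, , drop = FALSE], 1L)
      e <- nb$idx[1, 1]
      vv <- (index$vote_ptr[e] + 1L):index$vote_ptr[e + 1L]
      sel <- sort(unique(index$vote_id[vv]))
    }
    out[[r]] <- index$ids[sel]
  }
  out
}

#' Classify raw reads with the hybrid kNN -> HMM classifier
#'
#' For each read, takes the kNN shortlist of up to `h` candidate dye
#' sequences, computes the HMM forward likelihood for each candidate, and
#' normalizes the posterior over the shortlist only (truncated Bayes, with
#' the same source-peptide-count prior weights as [classify_bayes()]
#' restricted to the shortlist). This keeps the accuracy of the Bayesian
#' HMM classifier at a cost close to the kNN classifier.
#'
#' @param reads Matrix `n x T*C` or a `raw_read_set`.
#' @param index A [build_knn_index()] object.
#' @param models A [build_hmm_set()] list covering the reference.
#' @param k,sigma,h kNN shortlist parameters (defaults 10000, 0.5, 1000).
#' @param cutoff HMM pruning cutoff (default 5).
#' @param priors Optional prior weights named by dye_seq_id.
#' @param n_top Ranked candidates to keep per read.
#' @return Data.frame PRM table: `read`, `rank`, `dye_seq_id`, `score`.
#' @export
classify_hybrid <- function(reads, index, models, k = 10000, sigma = 0.5,
                            h = 1000, cutoff = 5, priors = NULL,
                            n_top = 1L) {
  y <- if (is.matrix(reads)) reads else reads$y
  short <- shortlist_candidates(index, reads, k = k, sigma = sigma, h = h)
  read_id <- rep(seq_along(short), lengths(short))
  cand <- unlist(short, use.names = FALSE)
  loglik <- numeric(length(cand))
  for (id in unique(cand)) {
    rows <- which(cand == id)
    loglik[rows] <- forward_batch(models[[as.character(id)]], y,
                                  read_id[rows], cutoff)
  }
  if (is.null(priors)) priors <- model_prior_weights(models)
  triplets_to_prms(read_id, cand, loglik,
                   prior_log = log(priors[as.character(cand)]),
                   n_top = n_top)
}
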