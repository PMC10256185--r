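#' Enumerate the reduced HMM state space for a dye sequence
#'
#' Instead of tracking which specific residues still carry fluorophores
#' (exponentially many "physical" states), the reduced model tracks only the
#' number of successfully removed residues `e*` and the per-channel counts of
#' surviving fluorophores `l_c`, plus one absorbing DETACHED state. For each
#' `e* = 0..E_max` (with `E_max = min(len, T - 1)`), `l_c` ranges over
#' `0..n_c(e*)` where `n_c(e)` counts labeled positions of channel `c`
#' strictly after the first `e` residues, so the state count is
#' `1 + sum_e prod_c (n_c(e) + 1)`.
#'
#' @param code Dye-seq code string (trailing '.' already trimmed).
#' @param n_timesteps Number of imaging timesteps `T`.
#' @param n_channels Number of channels; defaults to the channels present.
#' @return A `hmm_states` list: `estar` (integer, -1 for DETACHED), `ell`
#'   (`n_states x C` integer matrix; zero row for DETACHED), `n_after`
#'   (the `n_c(e)` table), `detached` (index of the DETACHED state), and an
#'   index lookup `index_of(estar, ell)`.
#' @export
enumerate_states <- function(code, n_timesteps, n_channels = NULL) {
  n_after <- dye_counts_after(code, n_channels)
  C <- ncol(n_after)
  len <- nrow(n_after) - 1L
  if (sum(n_after[1, ]) == 0L) stop("all-dark dye sequence")
  e_max <- min(len, n_timesteps - 1L)
  estar <- integer(0)
  ell <- matrix(integer(0), 0, C)
  for (e in 0:e_max) {
    grids <- lapply(seq_len(C), function(ch) 0:n_after[e + 1L, ch])
    g <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
    estar <- c(estar, rep(e, nrow(g)))
    ell <- rbind(ell, g)
  }
  n_att <- length(estar)
  estar <- c(estar, -1L)                      # DETACHED sentinel
  ell <- rbind(ell, rep(0L, C))
  dimnames(ell) <- NULL
  storage.mode(ell) <- "integer"
  key <- paste(estar[seq_len(n_att)], apply(ell[seq_len(n_att), , drop = FALSE],
                                            1, paste, collapse = ","))
  lookup <- stats::setNames(seq_len(n_att), key)
  index_of <- function(e, l) {
    unname(lookup[paste(e, paste(l, collapse = ","))])
  }
  structure(list(estar = as.integer(estar), ell = ell, n_after = n_after,
                 code = code, e_max = e_max, n_states = n_att + 1L,
                 detached = n_att + 1L, index_of = index_of),
            class = "hmm_states")
}

#' Initial state distribution
#'
#' Before sequencing, each of the `n_c(0)` fluorophores of channel `c` is
#' independently present with probability `1 - m_c` (the dud rate removes it).
#' All mass sits on `e* = 0` states with independent binomial channel counts.
#'
#' @param space An [enumerate_states()] object.
#' @param params A [seq_params()] object.
#' @return Probability vector over states (sums to 1).
#' @export
initial_distribution <- function(space, params) {
  pi0 <- numeric(space$n_states)
  at0 <- which(space$estar == 0L)
  n0 <- space$n_after[1, ]
  for (i in at0) {
    pr <- 1
    for (ch in seq_along(n0)) {
      pr <- pr * dbinom(space$ell[i, ch], n0[ch], 1 - params$m[ch])
    }
    pi0[i] <- pr
  }
  pi0
}

#' Sparse dye-loss transition factor for one channel
#'
#' Between timesteps every surviving fluorophore of channel `c`
#' photobleaches independently with probability `p_c`, so within a fixed
#' `(e*, other channels)` block the count drops `l -> j` with binomial
#' probability `choose(l, j) (1-p)^j p^(l-j)`. All other coordinates (and
#' DETACHED) are untouched. Matrices are column-stochastic in the orientation
#' `f_new = M %*% f` (entry `M[i, j] = P(next = i | current = j)`).
#'
#' @param space An [enumerate_states()] object.
#' @param channel Channel index (1-based).
#' @param p Per-cycle dye-loss probability for this channel.
#' @return A `dgCMatrix` operator.
#' @export
dye_loss_factor <- function(space, channel, p) {
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_len(space$n_states)) {
    if (space$estar[j] < 0L) {             # DETACHED
      ii <- c(ii, j); jj <- c(jj, j); xx <- c(xx, 1)
      next
    }
    l <- space$ell[j, channel]
    for (tgt in 0:l) {
      lnew <- space$ell[j, ]
      lnew[channel] <- tgt
      i <- space$index_of(space$estar[j], lnew)
      ii <- c(ii, i); jj <- c(jj, j)
      xx <- c(xx, dbinom(tgt, l, 1 - p))
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(space$n_states, space$n_states))
}

#' Sparse Edman-degradation transition factor
#'
#' With probability `e_rate` the Edman cycle fails and nothing changes. With
#' probability `1 - e_rate` the N-terminal-most remaining residue (position
#' `e* + 1` of the code) is removed. If that position is labeled with channel
#' `c`, one of the `n_c(e*)` remaining labeled positions of that channel is
#' the removed one; by exchangeability of surviving fluorophores the count
#' drops with probability `l_c / n_c(e*)` and stays otherwise. Unlabeled
#' removals leave counts unchanged. `e* = E_max` is absorbing for this factor.
#'
#' @param space An [enumerate_states()] object.
#' @param e_rate Edman failure probability.
#' @return A `dgCMatrix` operator (column-stochastic).
#' @export
edman_factor <- function(space, e_rate) {
  chars <- strsplit(space$code, "")[[1]]
  chan_at <- match(chars, channel_chars)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  for (j in seq_len(space$n_states)) {
    e <- space$estar[j]
    if (e < 0L || e >= space$e_max) {        # DETACHED or no residues/cycles left
      add(j, j, 1)
      next
    }
    if (e_rate > 0) add(j, j, e_rate)
    ch <- chan_at[e + 1L]                    # residue being removed
    l <- space$ell[j, ]
    if (is.na(ch)) {
      add(space$index_of(e + 1L, l), j, 1 - e_rate)
    } else {
      n_now <- space$n_after[e + 1L, ch]
      p_rm <- l[ch] / n_now
      if (p_rm > 0) {
        lr <- l; lr[ch] <- lr[ch] - 1L
        add(space$index_of(e + 1L, lr), j, (1 - e_rate) * p_rm)
      }
      if (p_rm < 1) {
        add(space$index_of(e + 1L, l), j, (1 - e_rate) * (1 - p_rm))
      }
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(space$n_states, space$n_states))
}

#' Sparse peptide-detachment transition factor
#'
#' Every attached state moves to the absorbing DETACHED state with
#' probability `d` and stays put otherwise.
#'
#' @param space An [enumerate_states()] object.
#' @param d Per-cycle detachment probability.
#' @return A `dgCMatrix` operator (column-stochastic).
#' @export
detach_factor <- function(space, d) {
  ns <- space$n_states
  att <- which(space$estar >= 0L)
  ii <- c(att, rep(space$detached, length(att) + 1L))
  jj <- c(att, att, space$detached)
  xx <- c(rep(1 - d, length(att)), rep(d, length(att)), 1)
  keep <- xx != 0
  Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = xx[keep],
                       dims = c(ns, ns))
}

#' Build the reduced HMM for one dye sequence
#'
#' Assembles state space, initial distribution, the factored transition
#' operators in application order (detachment, then Edman, then per-channel
#' dye loss — mirroring the simulator's event order), and their composed
#' one-step dense-equivalent transition matrix.
#'
#' @param code Dye-seq code string.
#' @param params A [seq_params()] object.
#' @return A `pep_hmm` list: `space`, `init`, `factors` (list of sparse
#'   operators in application order), `trans` (their product, the one-step
#'   transition matrix), `params`, `code`.
#' @export
build_hmm <- function(code, params) {
  space <- enumerate_states(code, params$n_timesteps, params$n_channels)
  factors <- c(list(detach = detach_factor(space, params$d),
                    edman = edman_factor(space, params$e)),
               stats::setNames(
                 lapply(seq_len(params$n_channels), function(ch) {
                   dye_loss_factor(space, ch, params$p[ch])
                 }),
                 paste0("dye_loss_", seq_len(params$n_channels) - 1L)))
  trans <- Reduce(function(acc, f) f %*% acc, factors)
  structure(list(space = space, init = initial_distribution(space, params),
                 factors = factors, trans = trans, params = params,
                 code = code, prior_weight = 1),
            class = "pep_hmm")
}

#' @export
print.pep_hmm <- function(x, ...) {
  cat(sprintf("<pep_hmm> code '%s': %d states, T=%d, C=%d\n", x$code,
              x$space$n_states, x$params$n_timesteps, x$params$n_channels))
  invisible(x)
}

#' Diagonal emission weights for one observation
#'
#' The probability density of observing intensities `y` (one value per
#' channel) from a state with surviving counts `l_c` is the product over
#' channels of Normal densities with mean `l_c mu_c` and variance
#' `sigma_bg_c^2 + l_c sigma_c^2`. DETACHED emits background only (all
#' `l_c = 0`).
#'
#' @param space An [enumerate_states()] object.
#' @param y Numeric vector of length `C`.
#' @param params A [seq_params()] object.
#' @return Numeric vector of per-state densities.
#' @export
emission_weights <- function(space, y, params) {
  if (any(!is.finite(y))) stop("non-finite observation")
  stopifnot(length(y) == ncol(space$ell))
  w <- rep(1, space$n_states)
  for (ch in seq_len(ncol(space$ell))) {
    l <- space$ell[, ch]
    w <- w * dnorm(y[ch], l * params$mu[ch],
                   sqrt(params$sigma_bg[ch]^2 + l * params$sigma[ch]^2))
  }
  w
}

#' Per-channel pruning ranges for one observation
#'
#' Keeps fluorophore counts `l` whose predicted intensity is within
#' `cutoff` standard deviations of the observed value:
#' `|y_c - l mu_c| <= cutoff * sqrt(sigma_bg_c^2 + l sigma_c^2)`. The kept
#' set is completed to a contiguous range and never left empty (fallback: the
#' count nearest to `y_c / mu_c`).
#'
#' @param y Numeric vector of length `C`.
#' @param params A [seq_params()] object.
#' @param cutoff Positive pruning cutoff (z-score-like; `Inf` disables).
#' @param n_max Integer vector of maximal counts per channel.
#' @return List of length `C`; element `c` is the kept range `lo:hi`
#'   (0-based counts).
#' @export
prune_ranges <- function(y, params, cutoff, n_max) {
  stopifnot(cutoff > 0, length(y) == length(n_max))
  lapply(seq_along(y), function(ch) {
    l <- 0:n_max[ch]
    sd_l <- sqrt(params$sigma_bg[ch]^2 + l * params$sigma[ch]^2)
    keep <- abs(y[ch] - l * params$mu[ch]) <= cutoff * sd_l
    if (!any(keep)) {
      nearest <- l[which.min(abs(y[ch] - l * params$mu[ch]))]
      return(nearest:nearest)
    }
    min(l[keep]):max(l[keep])
  })
}

#' HMM forward likelihood of a raw read given a dye sequence
#'
#' Runs the forward algorithm `f(t) = O(t) * (M f(t-1))` with `f(0) = O(0) *
#' init`, where `M` is applied as the product of the factored sparse
#' operators, and returns `sum_i f_i(T-1) = p(y_{0:T-1} | z)`. With a finite
#' `cutoff`, emission weights of states whose per-channel counts fall outside
#' the [prune_ranges()] of the current observation are zeroed, restricting
#' each step to plausible states.
#'
#' @param model A [build_hmm()] object.
#' @param y Observation matrix `T x C` (or flattened length `T*C`, time-major).
#' @param cutoff Pruning cutoff (default `Inf`: exact forward).
#' @return Likelihood (non-negative scalar) with attribute `log_likelihood`.
#' @export
forward_likelihood <- function(model, y, cutoff = Inf) {
  Tn <- model$params$n_timesteps; C <- model$params$n_channels
  if (is.matrix(y) && nrow(y) == Tn && ncol(y) == C) {
    yf <- as.numeric(t(y))
  } else if (length(y) == Tn * C) {
    yf <- as.numeric(y)
  } else {
    stop("observation shape does not match model (T=", Tn, ", C=", C, ")")
  }
  ll <- hmm_forward_cpp(model$factors$detach, model$factors$edman,
                        unname(model$factors[-(1:2)]),
                        model$init, model$space$ell,
                        matrix(yf, nrow = 1),
                        model$params$mu, model$params$sigma,
                        model$params$sigma_bg, cutoff)[1]
  structure(exp(ll), log_likelihood = ll)
}

# Pure-R reference forward pass over the factored operators (used by tests
# and as a readable specification of the C++ core).
forward_likelihood_r <- function(model, y, cutoff = Inf, use_dense = FALSE) {
  Tn <- model$params$n_timesteps
  if (!is.matrix(y)) y <- matrix(y, Tn, model$params$n_channels, byrow = TRUE)
  space <- model$space
  n_max <- apply(space$ell, 2, max)
  emis <- function(t) {
    w <- emission_weights(space, y[t, ], model$params)
    if (is.finite(cutoff)) {
      rng <- prune_ranges(y[t, ], model$params, cutoff, n_max)
      for (ch in seq_along(rng)) {
        w[space$ell[, ch] < min(rng[[ch]]) | space$ell[, ch] > max(rng[[ch]])] <- 0
      }
    }
    w
  }
  f <- model$init * emis(1)
  logscale <- 0
  if (Tn > 1L) {
    for (t in 2:Tn) {
      s <- sum(f)
      if (s <= 0) return(structure(0, log_likelihood = -Inf))
      logscale <- logscale + log(s)
      f <- f / s
      if (use_dense) {
        f <- as.numeric(model$trans %*% f)
      } else {
        for (fac in model$factors) f <- as.numeric(fac %*% f)
      }
      f <- f * emis(t)
    }
  }
  lik <- sum(f)
  structure(lik * exp(logscale), log_likelihood = log(lik) + logscale)
}

#' Bayesian posterior over candidate dye sequences
#'
#' Normalizes `likelihood * prior` over the provided candidate set (Bayesian
#' inversion). If every product is zero the posterior falls back to uniform
#' over the set, flagged by attribute `degenerate = TRUE` with a warning.
#'
#' @param likelihoods Named numeric vector of `p(y | z)`.
#' @param priors Prior weights (default uniform); recycled and renormalized.
#' @return Posterior vector summing to 1.
#' @export
posterior_scores <- function(likelihoods, priors = NULL) {
  n <- length(likelihoods)
  stopifnot(n >= 1)
  if (is.null(priors)) priors <- rep(1 / n, n)
  priors <- rep_len(priors, n) / sum(priors)
  w <- likelihoods * priors
  tot <- sum(w)
  if (tot <= 0) {
    warning("all candidate likelihoods are zero; returning uniform posterior")
    return(structure(rep(1 / n, n), names = names(likelihoods),
                     degenerate = TRUE))
  }
  structure(w / tot, names = names(likelihoods))
}

#' Build reduced HMMs for every dye sequence in a reference
#'
#' Each model carries a prior weight equal to its number of unique source
#' peptides: sampling peptides uniformly from the reference makes a merged
#' dye sequence a priori as likely as the peptides it collapses, and the
#' default classifier priors use these weights (see [classify_bayes()]).
#'
#' @param dye_seqs A `dye_seq_set`.
#' @param params A [seq_params()] object.
#' @return Named list of [build_hmm()] models keyed by `dye_seq_id`.
#' @export
build_hmm_set <- function(dye_seqs, params) {
  models <- lapply(seq_len(nrow(dye_seqs)), function(i) {
    m <- build_hmm(dye_seqs$code[i], params)
    if (!is.null(dye_seqs$peptides)) {
      m$prior_weight <- length(unique(dye_seqs$peptides[[i]]))
    }
    m
  })
  names(models) <- as.character(dye_seqs$dye_seq_id)
  models
}

# Batched log-likelihoods: one model against a subset of reads.
forward_batch <- function(model, y_flat, rows, cutoff) {
  hmm_forward_cpp(model$factors$detach, model$factors$edman,
                  unname(model$factors[-(1:2)]),
                  model$init, model$space$ell,
                  y_flat[rows, , drop = FALSE],
                  model$params$mu, model$params$sigma,
                  model$params$sigma_bg, cutoff)
}

# Turn a (read, candidate, loglik) triplet table into top-ranked PRMs with
# posterior scores normalized per read over its candidate set.
triplets_to_prms <- function(read, cand, loglik, prior_log = NULL, n_top = 1L) {
  dt <- data.table::data.table(read = read, cand = cand, loglik = loglik)
  if (!is.null(prior_log)) dt$loglik <- dt$loglik + prior_log
  dt[, `:=`(mx = max(loglik)), by = "read"]
  dt[, `:=`(w = exp(loglik - mx))]
  dt[, `:=`(score = w / sum(w)), by = "read"]
  data.table::setorder(dt, read, -score, cand)
  dt[, `:=`(rank = seq_len(.N)), by = "read"]
  out <- dt[dt$rank <= n_top, c("read", "rank", "cand", "score")]
  data.table::setnames(out, "cand", "dye_seq_id")
  as.data.frame(out)
}

#' Classify raw reads with the full Bayesian HMM classifier
#'
#' Computes the forward likelihood of each read under every dye sequence in
#' the reference and reports the maximum-posterior peptide-read match (PRM)
#' per read, with the posterior normalized over the whole reference. The
#' default prior weights each dye sequence by its number of source peptides
#' (uniform over peptides, matching how experiments sample molecules); pass
#' explicit `priors` to override. Ties break toward the lowest dye-seq id.
#'
#' @param reads A `raw_read_set` (or matrix `n x T*C`).
#' @param models A [build_hmm_set()] list.
#' @param cutoff Pruning cutoff (default 5; `Inf` disables pruning).
#' @param priors Optional prior weights named by dye_seq_id (normalization
#'   is immaterial).
#' @param n_top Number of ranked candidates to keep per read.
#' @return Data.frame PRM table: `read`, `rank`, `dye_seq_id`, `score`.
#' @export
classify_bayes <- function(reads, models, cutoff = 5, priors = NULL,
                           n_top = 1L) {
  stopifnot(length(models) >= 1)
  y <- if (is.matrix(reads)) reads else reads$y
  n <- nrow(y)
  ids <- as.integer(names(models))
  ll <- matrix(0, n, length(models))
  for (mi in seq_along(models)) {
    ll[, mi] <- forward_batch(models[[mi]], y, seq_len(n), cutoff)
  }
  if (is.null(priors)) priors <- model_prior_weights(models)
  prior_log <- rep(log(priors[as.character(ids)]), each = n)
  triplets_to_prms(rep(seq_len(n), length(models)),
                   rep(ids, each = n), as.numeric(ll), prior_log, n_top)
}

model_prior_weights <- function(models) {
  w <- vapply(models, function(m) {
    if (is.null(m$prior_weight)) 1 else m$prior_weight
  }, numeric(1))
  stats::setNames(w, names(models))
}
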