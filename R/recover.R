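#' Recover sequencing error rates from designed simulations
#'
#' Runs one designed Monte Carlo experiment per parameter, each isolating a
#' single rate by zeroing the others, and returns closed-form
#' method-of-moments / maximum-likelihood estimates with standard errors:
#'
#' * `m` (dud rate): one-residue single-label peptide, all other rates zero;
#'   the fraction of tracks dark at `t = 0` is a binomial MLE of `m`.
#' * `e` (Edman failure): single label on the first residue, other rates
#'   zero, `T = 2`; the fraction still lit at `t = 1` estimates `e`.
#' * `d` (detachment): Edman always failing (`e = 1`), bleaching and duds
#'   zero, `T = 10`; the per-cycle signal-loss hazard is the geometric MLE
#'   (events / exposure cycles, right-censored at the last timestep).
#' * `p` (dye loss): `e = 1`, detachment and duds zero, `T = 2`; one minus
#'   the single-cycle survival fraction estimates `p`.
#' * `mu`, `sigma`: raw-read intensities of a single fluorophore at `t = 0`
#'   with duds off; the sample mean estimates `mu` and
#'   `sqrt(var - sigma_bg^2)` estimates `sigma` (delta-method SE).
#'
#' @param n Tracks/reads per experiment (default 1e5).
#' @param params Baseline [seq_params()]; each experiment copies it and
#'   zeroes the interfering rates. Only channel 1 is used.
#' @param seed Optional integer seed.
#' @return Data.frame: `param`, `truth`, `estimate`, `se`, `n`.
#' @export
recover_error_rates <- function(n = 1e5, params = seq_params(n_channels = 1),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 100)
  n <- as.integer(n)
  base <- params
  zero_but <- function(keep) {
    q <- base
    if (!"p" %in% keep) q$p[] <- 0
    if (!"m" %in% keep) q$m[] <- 0
    if (!"e" %in% keep) q$e <- 0
    if (!"d" %in% keep) q$d <- 0
    q
  }
  out <- list()

  # m: dark fraction at t=0 of a single-label track
  q <- zero_but("m"); q$n_timesteps <- 1L
  tr <- simulate_dye_tracks("0", n, q)
  dark <- mean(tr[, 1, 1] == 0L)
  out$m <- c(base$m[1], dark, sqrt(dark * (1 - dark) / n))

  # e: still lit at t=1 means the first Edman cycle failed
  q <- zero_but("e"); q$n_timesteps <- 2L
  tr <- simulate_dye_tracks("0", n, q)
  lit <- mean(tr[, 2, 1] == 1L)
  out$e <- c(base$e, lit, sqrt(lit * (1 - lit) / n))

  # d: geometric hazard of losing the signal when only detachment acts
  q <- zero_but("d"); q$e <- 1; q$n_timesteps <- 10L
  tr <- simulate_dye_tracks("0", n, q)
  lit_mat <- tr[, , 1] == 1L
  last <- ncol(lit_mat)
  # signal is monotone, so the number of lit logs is the cycle of loss
  lit_n <- rowSums(lit_mat)
  events <- sum(lit_n < last)
  trials <- sum(pmin(lit_n, last - 1L))
  dhat <- events / trials
  out$d <- c(base$d, dhat, sqrt(dhat * (1 - dhat) / trials))

  # p: one-cycle bleach survival with e = 1, d = 0
  q <- zero_but("p"); q$e <- 1; q$n_timesteps <- 2L
  tr <- simulate_dye_tracks("0", n, q)
  phat <- 1 - mean(tr[, 2, 1] == 1L)
  out$p <- c(base$p[1], phat, sqrt(phat * (1 - phat) / n))

  # mu and sigma from single-fluorophore radiometry at t=0
  q <- zero_but(character(0)); q$n_timesteps <- 1L
  tr <- simulate_dye_tracks("0", n, q)
  y <- flatten_tracks(emit_raw_reads(tr, q))[, 1]
  muhat <- mean(y)
  v <- stats::var(y)
  out$mu <- c(base$mu[1], muhat, sqrt(v / n))
  sigma2 <- v - base$sigma_bg[1]^2
  if (sigma2 <= 0) stop("degenerate design: no per-fluorophore variance signal")
  sighat <- sqrt(sigma2)
  se_var <- v * sqrt(2 / (n - 1))
  out$sigma <- c(base$sigma[1], sighat, se_var / (2 * sighat))

  data.frame(param = names(out),
             truth = vapply(out, `[`, numeric(1), 1),
             estimate = vapply(out, `[`, numeric(1), 2),
             se = vapply(out, `[`, numeric(1), 3),
             n = n, row.names = NULL)
}
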