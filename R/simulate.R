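#' Sequencing error-model parameters
#'
#' Collects the fluorosequencing error model: per-channel photobleaching/dye
#' destruction rate `p` (per cycle), per-channel missing-fluorophore ("dud")
#' rate `m`, Edman cycle failure rate `e`, peptide detachment rate `d` (per
#' cycle), per-channel mean single-fluorophore intensity `mu`, per-fluorophore
#' intensity standard deviation `sigma`, background standard deviation
#' `sigma_bg`, and the number of imaging timesteps `T`. Defaults are prior
#' estimates for the dye Atto647N used throughout: p = 0.05, m = 0.07,
#' e = 0.06, d = 0.05, mu = 1.0, sigma = 0.16, sigma_bg = 0.00667.
#'
#' @param p,m Per-channel rates in `[0, 1]`, recycled to `n_channels`.
#' @param e,d Scalar rates in `[0, 1]`.
#' @param mu,sigma,sigma_bg Per-channel intensity parameters (positive).
#' @param n_channels Number of fluorophore channels.
#' @param n_timesteps Number of imaging timesteps `T` (>= 1).
#' @return A `seq_params` object.
#' @export
seq_params <- function(p = 0.05, m = 0.07, e = 0.06, d = 0.05,
                       mu = 1.0, sigma = 0.16, sigma_bg = 0.00667,
                       n_channels = 3, n_timesteps = 10) {
  C <- as.integer(n_channels)
  stopifnot(C >= 1L, n_timesteps >= 1L)
  x <- list(p = rep_len(p, C), m = rep_len(m, C), e = e, d = d,
            mu = rep_len(mu, C), sigma = rep_len(sigma, C),
            sigma_bg = rep_len(sigma_bg, C),
            n_channels = C, n_timesteps = as.integer(n_timesteps))
  rates <- c(x$p, x$m, x$e, x$d)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (any(x$mu <= 0) || any(x$sigma <= 0) || any(x$sigma_bg <= 0)) {
    stop("mu, sigma and sigma_bg must be positive")
  }
  structure(x, class = "seq_params")
}

#' @export
print.seq_params <- function(x, ...) {
  cat(sprintf("<seq_params> C=%d T=%d e=%g d=%g\n", x$n_channels,
              x$n_timesteps, x$e, x$d))
  cat("  p:", x$p, "| m:", x$m, "\n")
  cat("  mu:", x$mu, "| sigma:", x$sigma, "| sigma_bg:", x$sigma_bg, "\n")
  invisible(x)
}

parse_code <- function(code) {
  chars <- strsplit(code, "")[[1]]
  chan <- match(chars, channel_chars)
  list(len = length(chars), pos = which(!is.na(chan)),
       chan = chan[!is.na(chan)])
}

# Geometric lifetime: number of per-cycle survival trials passed before the
# first event with per-cycle probability `prob` (Inf when prob == 0).
geom_life <- function(n, prob) {
  if (prob <= 0) rep(Inf, n)
  else if (prob >= 1) rep(0L, n)
  else stats::rgeom(n, prob)
}

#' Simulate dye tracks for one dye sequence
#'
#' Monte Carlo simulation of the physical sequencing process for `n`
#' molecules. Before sequencing each fluorophore is a dud with probability
#' `m_c`. Fluorophore counts are logged at each timestep `t = 0..T-1`; between
#' logs the molecule detaches with probability `d`, the N-terminal residue
#' (with any attached fluorophore) is removed with probability `1 - e`, and
#' every surviving fluorophore photobleaches with probability `p_c`. Each
#' fluorophore position is tracked explicitly, so per-channel counts are
#' non-increasing in time and zero after detachment.
#'
#' @param code Dye-seq code string.
#' @param n Number of molecules to simulate.
#' @param params A [seq_params()] object.
#' @return Integer array `n x T x C` of fluorophore counts.
#' @export
simulate_dye_tracks <- function(code, n, params) {
  stopifnot(inherits(params, "seq_params"), n >= 1)
  info <- parse_code(code)
  Tn <- params$n_timesteps; C <- params$n_channels
  L <- length(info$pos)
  if (L == 0L) stop("dye sequence has no labeled positions")
  if (max(info$chan) > C) stop("code uses more channels than params define")
  # dud status and bleach lifetime per labeled position
  lit <- matrix(stats::runif(n * L) >= rep(params$m[info$chan], each = n), n, L)
  bleach <- matrix(0, n, L)
  for (j in seq_len(L)) bleach[, j] <- geom_life(n, params$p[info$chan[j]])
  detach <- geom_life(n, params$d)
  # cumulative Edman successes after t cycles (S[, t + 1] = S_t, S_0 = 0)
  S <- matrix(0L, n, Tn)
  if (Tn > 1L) {
    for (t in 2:Tn) {
      S[, t] <- S[, t - 1L] + (stats::runif(n) < (1 - params$e))
    }
  }
  counts <- array(0L, dim = c(n, Tn, C))
  for (t in seq_len(Tn)) {       # log index t-1
    tt <- t - 1L
    for (j in seq_len(L)) {
      present <- lit[, j] & (bleach[, j] >= tt) & (S[, t] < info$pos[j]) &
        (detach >= tt)
      ch <- info$chan[j]
      counts[, t, ch] <- counts[, t, ch] + present
    }
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Convert dye tracks to raw intensity reads
#'
#' Each count cell with `Lambda` fluorophores of channel `c` is replaced by a
#' draw from Normal(`Lambda * mu_c`, `sigma_bg_c^2 + Lambda * sigma_c^2`),
#' modeling per-fluorophore brightness variation on top of background noise.
#'
#' @param tracks Integer array `n x T x C` from [simulate_dye_tracks()].
#' @param params A [seq_params()] object.
#' @return Numeric array `n x T x C` of intensities.
#' @export
emit_raw_reads <- function(tracks, params) {
  dm <- dim(tracks)
  stopifnot(length(dm) == 3L, dm[3] == params$n_channels)
  y <- array(0, dim = dm)
  for (ch in seq_len(dm[3])) {
    lam <- tracks[, , ch, drop = FALSE]
    sd_cell <- sqrt(params$sigma_bg[ch]^2 + lam * params$sigma[ch]^2)
    y[, , ch] <- lam * params$mu[ch] + stats::rnorm(length(lam), 0, sd_cell)
  }
  y
}

# Flatten n x T x C count/intensity arrays to n x (T*C), time-major:
# column index = (t-1)*C + c.
flatten_tracks <- function(a) {
  dm <- dim(a)
  matrix(aperm(a, c(1L, 3L, 2L)), nrow = dm[1], ncol = dm[2] * dm[3])
}

unflatten_tracks <- function(m, T, C) {
  aperm(array(m, dim = c(nrow(m), C, T)), c(1L, 3L, 2L))
}

#' Generate a deduplicated kNN training set of dye tracks
#'
#' Simulates `n_per_peptide` dye tracks for every dye sequence in the
#' reference, discards all-dark tracks (zero fluorophores at every timestep;
#' unobservable in a real experiment), and merges bit-identical tracks into
#' single entries holding a multiplicity and per-dye-sequence production
#' counts.
#'
#' @param dye_seqs A `dye_seq_set` (or data.frame with `dye_seq_id`, `code`).
#' @param n_per_peptide Simulated tracks per dye sequence (standard
#'   protocol: 1000).
#' @param params A [seq_params()] object.
#' @param seed Optional integer seed.
#' @return A `dye_track_set`: list with `T`, `C`, `counts` (matrix
#'   `n_entries x T*C`, time-major flattening), `multiplicity`, `votes`
#'   (data.frame `entry`, `dye_seq_id`, `count`), and `n_discarded`.
#' @export
generate_training_set <- function(dye_seqs, n_per_peptide, params, seed = NULL) {
  stopifnot(n_per_peptide >= 1)
  if (!is.null(seed)) set.seed(seed)
  Tn <- params$n_timesteps; C <- params$n_channels
  blocks <- vector("list", nrow(dye_seqs))
  for (i in seq_len(nrow(dye_seqs))) {
    tr <- simulate_dye_tracks(dye_seqs$code[i], n_per_peptide, params)
    blocks[[i]] <- flatten_tracks(tr)
  }
  flat <- do.call(rbind, blocks)
  id <- rep(dye_seqs$dye_seq_id, each = n_per_peptide)
  dark <- rowSums(flat) == 0L
  n_discarded <- sum(dark)
  flat <- flat[!dark, , drop = FALSE]
  id <- id[!dark]

  dt <- data.table::as.data.table(flat)
  keycols <- names(dt)
  dt$..dsid <- id
  agg <- dt[, list(count = .N), by = c(keycols, "..dsid")]
  data.table::setorderv(agg, c(keycols, "..dsid"))
  ent <- agg[, list(multiplicity = sum(count)), by = keycols]
  counts <- as.matrix(ent[, keycols, with = FALSE])
  dimnames(counts) <- NULL
  storage.mode(counts) <- "integer"
  entry_key <- do.call(paste, c(as.data.frame(counts), sep = ","))
  agg_key <- do.call(paste, c(agg[, keycols, with = FALSE], sep = ","))
  votes <- data.frame(entry = match(agg_key, entry_key),
                      dye_seq_id = agg$..dsid, count = agg$count)
  votes <- votes[order(votes$entry, votes$dye_seq_id), , drop = FALSE]
  rownames(votes) <- NULL
  structure(list(T = Tn, C = C, counts = counts,
                 multiplicity = as.integer(ent$multiplicity),
                 votes = votes, n_discarded = n_discarded),
            class = "dye_track_set")
}

#' @export
print.dye_track_set <- function(x, ...) {
  cat(sprintf("<dye_track_set> %d unique tracks (T=%d, C=%d), %d molecules, %d all-dark discarded\n",
              nrow(x$counts), x$T, x$C, sum(x$multiplicity), x$n_discarded))
  invisible(x)
}

#' Generate a labeled test set of raw reads
#'
#' Draws peptides uniformly with replacement from the reference source table
#' (a dye sequence produced by several peptides is drawn proportionally more
#' often), simulates sequencing, converts to raw intensity reads, and discards
#' reads whose underlying dye track is all-dark, resampling until exactly
#' `n_reads` retained reads are collected.
#'
#' @param dye_seqs A `dye_seq_set` from [make_dye_seqs()].
#' @param n_reads Number of retained reads required.
#' @param params A [seq_params()] object.
#' @param seed Optional integer seed.
#' @param max_rounds Abort after this many resampling rounds without filling
#'   the quota (guards against all-dark regimes such as `m = 1`).
#' @return A `raw_read_set`: list with `T`, `C`, `y` (matrix `n_reads x T*C`,
#'   time-major), and truth columns `truth` (dye_seq_id), `truth_peptide`,
#'   `truth_protein`.
#' @export
generate_test_set <- function(dye_seqs, n_reads, params, seed = NULL,
                              max_rounds = 100L) {
  stopifnot(n_reads >= 1)
  if (nrow(dye_seqs) == 0L) stop("empty dye-sequence reference")
  if (!is.null(seed)) set.seed(seed)
  Tn <- params$n_timesteps; C <- params$n_channels
  # one sampling unit per (peptide, protein) source pair
  units <- data.frame(
    dye_seq_id = rep(dye_seqs$dye_seq_id, lengths(dye_seqs$peptides)),
    peptide = unlist(dye_seqs$peptides, use.names = FALSE),
    protein = unlist(dye_seqs$proteins, use.names = FALSE))
  # sample a peptide uniformly over unique peptides, then a parent protein
  upep <- unique(units$peptide)
  rows_by_pep <- split(seq_len(nrow(units)), factor(units$peptide, upep))
  ys <- list(); truth <- list(); got <- 0L
  for (round in seq_len(max_rounds)) {
    need <- n_reads - got
    if (need <= 0L) break
    draw_pep <- sample.int(length(upep), need, replace = TRUE)
    rows <- vapply(rows_by_pep[draw_pep], function(cand) {
      if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
    }, integer(1))
    batch <- units[rows, , drop = FALSE]
    for (dsid in unique(batch$dye_seq_id)) {
      sel <- which(batch$dye_seq_id == dsid)
      code <- dye_seqs$code[match(dsid, dye_seqs$dye_seq_id)]
      tr <- simulate_dye_tracks(code, length(sel), params)
      flat_tr <- flatten_tracks(tr)
      keep <- rowSums(flat_tr) > 0L
      if (!any(keep)) next
      yy <- flatten_tracks(emit_raw_reads(
        tr[keep, , , drop = FALSE], params))
      ys[[length(ys) + 1L]] <- yy
      truth[[length(truth) + 1L]] <- batch[sel[keep], , drop = FALSE]
      got <- got + sum(keep)
    }
    if (got >= n_reads) break
  }
  if (got < n_reads) {
    stop("could not collect ", n_reads, " observable reads in ", max_rounds,
         " rounds (all-dark rate too high?)")
  }
  y <- do.call(rbind, ys)[seq_len(n_reads), , drop = FALSE]
  tr <- do.call(rbind, truth)[seq_len(n_reads), , drop = FALSE]
  structure(list(T = Tn, C = C, y = y,
                 truth = tr$dye_seq_id, truth_peptide = tr$peptide,
                 truth_protein = tr$protein),
            class = "raw_read_set")
}

#' @export
print.raw_read_set <- function(x, ...) {
  cat(sprintf("<raw_read_set> %d reads (T=%d, C=%d)%s\n", nrow(x$y), x$T, x$C,
              if (!is.null(x$truth)) ", with truth labels" else ""))
  invisible(x)
}
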