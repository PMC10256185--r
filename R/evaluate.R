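#' Precision-recall curve from scored predictions
#'
#' Sweeps descending score thresholds (tied scores processed as one block).
#' At each threshold, precision = correct predictions at or above it divided
#' by predictions at or above it; recall = correct predictions at or above it
#' divided by `n_total`. `correct` may be fractional (see
#' [predicted_pr_curve()]).
#'
#' @param score Numeric prediction scores.
#' @param correct Logical or fractional correctness per prediction.
#' @param n_total Recall denominator (default: number of predictions).
#' @return A `pr_curve` data.frame: `threshold`, `recall`, `precision`.
#' @export
pr_curve <- function(score, correct, n_total = length(score)) {
  stopifnot(length(score) == length(correct))
  ord <- order(-score)
  s <- score[ord]; g <- as.numeric(correct[ord])
  cum_correct <- cumsum(g)
  cum_n <- seq_along(g)
  block_end <- which(c(s[-1] != s[-length(s)], TRUE))
  out <- data.frame(threshold = s[block_end],
                    recall = cum_correct[block_end] / n_total,
                    precision = cum_correct[block_end] / cum_n[block_end])
  class(out) <- c("pr_curve", "data.frame")
  out
}

#' Predicted precision-recall curve from scores alone
#'
#' Treats each prediction as fractionally correct with probability equal to
#' its score, yielding a truth-free estimate of the PR curve (and hence of
#' the false discovery rate, one minus precision) usable on real data.
#'
#' @param score Numeric prediction scores.
#' @param n_total Recall denominator (default: number of predictions).
#' @return A `pr_curve` data.frame.
#' @export
predicted_pr_curve <- function(score, n_total = length(score)) {
  pr_curve(score, score, n_total = n_total)
}

#' Precision at given recall levels (step interpolation)
#'
#' Returns the precision of the highest-threshold sweep point whose recall
#' reaches each requested level (`NA` beyond the curve's maximum recall).
#' Used to compare two PR curves on a common recall grid.
#'
#' @param curve A [pr_curve()] object.
#' @param recall Numeric vector of recall levels.
#' @return Numeric vector of precisions.
#' @export
pr_at_recall <- function(curve, recall) {
  vapply(recall, function(r) {
    i <- which(curve$recall >= r)
    if (length(i) == 0L) NA_real_ else curve$precision[min(i)]
  }, numeric(1))
}

# mean absolute precision difference between two curves on a shared grid
pr_mean_abs_diff <- function(a, b, n_grid = 50L) {
  rmax <- min(max(a$recall), max(b$recall))
  grid <- seq(rmax / n_grid, rmax, length.out = n_grid)
  mean(abs(pr_at_recall(a, grid) - pr_at_recall(b, grid)))
}

#' Score-calibration table in equal-count buckets
#'
#' Sorts predictions by score, splits them into `n_buckets` equal-count
#' buckets (the remainder spread one-per-bucket over the leading buckets),
#' and reports each bucket's mean predicted score, empirical accuracy and
#' size. A well-calibrated classifier has both means close along the
#' diagonal.
#'
#' @param score Numeric prediction scores.
#' @param correct Logical correctness per prediction.
#' @param n_buckets Number of buckets (default 100). If there are fewer
#'   predictions than buckets the bucket count is reduced and the result is
#'   flagged with attribute `reduced = TRUE`.
#' @return Data.frame: `bucket`, `mean_score`, `accuracy`, `n`.
#' @export
calibration_table <- function(score, correct, n_buckets = 100L) {
  n <- length(score)
  stopifnot(n >= 1, length(correct) == n)
  reduced <- FALSE
  if (n < n_buckets) {
    n_buckets <- n
    reduced <- TRUE
    warning("fewer predictions than buckets; using ", n_buckets, " buckets")
  }
  ord <- order(score)
  base <- n %/% n_buckets
  sizes <- rep(base, n_buckets)
  rem <- n %% n_buckets
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  bucket <- rep(seq_len(n_buckets), times = sizes)
  s <- score[ord]; g <- as.numeric(correct[ord])
  out <- data.frame(
    bucket = seq_len(n_buckets),
    mean_score = as.numeric(tapply(s, bucket, mean)),
    accuracy = as.numeric(tapply(g, bucket, mean)),
    n = sizes)
  attr(out, "reduced") <- reduced
  out
}

#' Roll read-level matches up to peptide scores
#'
#' Each read contributes `score / n` to each of the `n` peptides that share
#' its winning dye sequence (penalizing ambiguous identifications); a
#' peptide's score is the maximum contribution over reads.
#'
#' @param prms PRM data.frame (`read`, `dye_seq_id`, `score`; rank-1 rows
#'   are used).
#' @param dye_seqs The `dye_seq_set` defining dye-seq -> peptide provenance.
#' @return Data.frame: `peptide`, `score`.
#' @export
score_peptides <- function(prms, dye_seqs) {
  if ("rank" %in% names(prms)) prms <- prms[prms$rank == 1L, , drop = FALSE]
  idx <- match(prms$dye_seq_id, dye_seqs$dye_seq_id)
  peps <- lapply(dye_seqs$peptides[idx], unique)
  n_pep <- lengths(peps)
  contrib <- data.frame(peptide = unlist(peps, use.names = FALSE),
                        value = rep(prms$score / n_pep, n_pep))
  agg <- tapply(contrib$value, contrib$peptide, max)
  data.frame(peptide = names(agg), score = as.numeric(agg),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Roll peptide scores up to protein scores
#'
#' Each peptide contributes `score / n` to each of its `n` parent proteins;
#' a protein's score is the maximum contribution over its peptides.
#'
#' @param peptide_scores Output of [score_peptides()].
#' @param peptide_map Data.frame of unique (`peptide`, `protein`) pairs
#'   (e.g. `attr(dye_seqs, "peptide_map")`).
#' @return Data.frame: `protein`, `score`.
#' @export
score_proteins <- function(peptide_scores, peptide_map) {
  n_prot <- table(peptide_map$peptide)
  m <- merge(peptide_scores, peptide_map, by = "peptide")
  m$value <- m$score / as.numeric(n_prot[m$peptide])
  agg <- tapply(m$value, m$protein, max)
  data.frame(protein = names(agg), score = as.numeric(agg),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read-, peptide- and protein-level PR curves for a labeled run
#'
#' Read-level: every retained read is a prediction and carries its own truth.
#' Peptide/protein level: predictions are the rolled-up entity scores; an
#' entity is correct if it truly generated at least one read; the recall
#' denominator is the number of entities truly present among the sampled
#' reads.
#'
#' @param prms PRM table with rank-1 rows.
#' @param reads The `raw_read_set` holding truth labels.
#' @param dye_seqs The `dye_seq_set` reference.
#' @return List of `pr_curve` objects: `read`, `peptide`, `protein`.
#' @export
level_pr_curves <- function(prms, reads, dye_seqs) {
  if ("rank" %in% names(prms)) prms <- prms[prms$rank == 1L, , drop = FALSE]
  stopifnot(nrow(prms) == nrow(reads$y))
  read_pr <- pr_curve(prms$score,
                      prms$dye_seq_id == reads$truth[prms$read],
                      n_total = nrow(reads$y))
  pep <- score_peptides(prms, dye_seqs)
  true_peps <- unique(reads$truth_peptide)
  pep_pr <- pr_curve(pep$score, pep$peptide %in% true_peps,
                     n_total = length(true_peps))
  prot <- score_proteins(pep, attr(dye_seqs, "peptide_map"))
  true_prots <- unique(reads$truth_protein)
  prot_pr <- pr_curve(prot$score, prot$protein %in% true_prots,
                      n_total = length(true_prots))
  list(read = read_pr, peptide = pep_pr, protein = prot_pr)
}
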