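#' Label schemes: protease plus fluorophore channel assignments
#'
#' A label scheme pairs a protease (which defines in-silico digestion) with an
#' ordered list of fluorophore channels, each channel being a set of amino
#' acids labeled with one dye color. Channel sets must be pairwise disjoint;
#' amino acids sharing a dye (e.g. aspartate and glutamate, which react
#' equivalently) are put in the same channel.
#'
#' @param protease One of `"trypsin"` (cleaves after K and R),
#'   `"cyanogen_bromide"` (after M), `"endopro"` (after A and P).
#' @param channels Character vector; element `c` holds the amino acids of
#'   channel `c - 1` as a string, e.g. `c("DE", "C", "Y")`.
#' @return A `label_scheme` object.
#' @examples
#' make_label_scheme("trypsin", c("DE", "C", "Y"))
#' @export
make_label_scheme <- function(protease = c("trypsin", "cyanogen_bromide", "endopro"),
                              channels = c("DE", "C", "Y")) {
  protease <- match.arg(protease)
  if (length(channels) < 1L) stop("at least one channel is required")
  sets <- lapply(channels, function(s) unique(strsplit(toupper(s), "")[[1]]))
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  all_lab <- unlist(sets)
  if (any(duplicated(all_lab))) stop("channel sets must be pairwise disjoint")
  if (!all(all_lab %in% aa20)) {
    stop("labeled amino acids must be canonical: ",
         paste(setdiff(all_lab, aa20), collapse = ", "))
  }
  structure(list(protease = protease, channels = sets),
            class = "label_scheme")
}

#' @export
print.label_scheme <- function(x, ...) {
  cat("<label_scheme> protease:", x$protease, "\n")
  for (i in seq_along(x$channels)) {
    cat("  channel", i - 1L, ":", paste(x$channels[[i]], collapse = ""), "\n")
  }
  invisible(x)
}

cleavage_residues <- function(protease) {
  switch(protease,
         trypsin = c("K", "R"),
         cyanogen_bromide = "M",
         endopro = c("A", "P"),
         stop("unknown protease: ", protease))
}

#' In-silico proteolytic digestion
#'
#' Cleaves a protein sequence immediately after every cleavage residue of the
#' protease (no missed cleavages, no positional exceptions). The concatenation
#' of the returned peptides always equals the input sequence.
#'
#' @param sequence Amino-acid string (non-canonical letters pass through but
#'   are never cleaved or labeled).
#' @param protease Protease name, see [make_label_scheme()].
#' @return Character vector of peptides.
#' @examples
#' digest("AKRMC", "trypsin")
#' @export
digest <- function(sequence, protease = "trypsin") {
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) == 0L) {
    stop("sequence must be a single non-empty string")
  }
  res <- cleavage_residues(protease)
  pat <- sprintf("(?<=[%s])", paste(res, collapse = ""))
  peps <- strsplit(toupper(sequence), pat, perl = TRUE)[[1]]
  peps[nzchar(peps)]
}

# Channel alphabet for dye-seq codes: '0'-'9' then 'A'-'Z' ('.' = unlabeled).
channel_chars <- c(as.character(0:9), LETTERS)

#' Convert a peptide into a dye-sequence code
#'
#' Each residue is replaced by its channel index character if labeled under
#' the scheme, or `'.'` if unlabeled. Trailing unlabeled residues are trimmed:
#' the instrument cannot observe residues after the last fluorophore, so
#' peptides that differ only in an unlabeled C-terminal tail share one code.
#'
#' @param peptide Amino-acid string.
#' @param scheme A [make_label_scheme()] object.
#' @return The code string, or `NA_character_` if no residue is labeled
#'   (an "all-dark", unobservable peptide).
#' @examples
#' label_peptide("DYCA", make_label_scheme("trypsin", c("DE", "C", "Y")))
#' @export
label_peptide <- function(peptide, scheme) {
  stopifnot(inherits(scheme, "label_scheme"))
  aa <- strsplit(toupper(peptide), "")[[1]]
  code <- rep(".", length(aa))
  for (c_idx in seq_along(scheme$channels)) {
    code[aa %in% scheme$channels[[c_idx]]] <- channel_chars[c_idx]
  }
  code <- sub("\\.+$", "", paste(code, collapse = ""))
  if (!nzchar(code)) NA_character_ else code
}

#' Per-channel label counts after partial degradation
#'
#' For a dye-seq code, returns the matrix `n[e + 1, c]` = number of labeled
#' positions of channel `c` strictly after the first `e` residues, for
#' `e = 0..len`. Non-increasing in `e`, with `n[len + 1, ] == 0`.
#'
#' @param code Dye-seq code string.
#' @param n_channels Number of channels (defaults to the largest channel
#'   present in the code plus one).
#' @return Integer matrix `(len + 1) x n_channels`.
#' @export
dye_counts_after <- function(code, n_channels = NULL) {
  chars <- strsplit(code, "")[[1]]
  chan <- match(chars, channel_chars)  # NA for '.'
  if (is.null(n_channels)) n_channels <- max(chan, 1L, na.rm = TRUE)
  len <- length(chars)
  n <- matrix(0L, len + 1L, n_channels)
  for (e in len:1) {
    n[e, ] <- n[e + 1L, ]
    if (!is.na(chan[e]) && chan[e] <= n_channels) {
      n[e, chan[e]] <- n[e, chan[e]] + 1L
    }
  }
  n
}

#' Build a deduplicated dye-sequence reference from a proteome
#'
#' Digests every protein with the scheme's protease, labels every peptide,
#' drops all-dark (unlabelable) peptides, and merges peptides whose trimmed
#' dye-seq codes coincide. Provenance is kept as (peptide, protein) source
#' pairs; identical peptides arising from different proteins contribute one
#' source pair per protein.
#'
#' @param proteins Named character vector of protein sequences (names are
#'   protein ids), or a data.frame with columns `protein` and `sequence`.
#' @param scheme A [make_label_scheme()] object.
#' @return A `dye_seq_set`: data.frame with columns `dye_seq_id` (integer),
#'   `code`, and list-columns `peptides` and `proteins` (parallel vectors, one
#'   element per source pair). Attributes: `scheme`, `n_channels`,
#'   `peptide_map` (unique peptide/protein pair table).
#' @export
make_dye_seqs <- function(proteins, scheme) {
  if (is.data.frame(proteins)) {
    seqs <- as.character(proteins$sequence)
    names(seqs) <- as.character(proteins$protein)
    proteins <- seqs
  }
  if (is.null(names(proteins)) || any(!nzchar(names(proteins)))) {
    stop("proteins must be named by protein id")
  }
  if (anyDuplicated(names(proteins))) stop("duplicate protein ids")
  pep <- character(0); prot <- character(0)
  for (id in names(proteins)) {
    p <- digest(proteins[[id]], scheme$protease)
    pep <- c(pep, p)
    prot <- c(prot, rep(id, length(p)))
  }
  # unique (peptide, protein) source pairs
  pairs <- unique(data.frame(peptide = pep, protein = prot,
                             stringsAsFactors = FALSE))
  upep <- unique(pairs$peptide)
  codes <- vapply(upep, label_peptide, character(1), scheme = scheme)
  keep <- !is.na(codes)
  code_of_pep <- stats::setNames(codes[keep], upep[keep])
  pairs <- pairs[pairs$peptide %in% names(code_of_pep), , drop = FALSE]
  pairs$code <- unname(code_of_pep[pairs$peptide])
  ucodes <- sort(unique(pairs$code))
  by_code <- split(pairs[c("peptide", "protein")], factor(pairs$code, ucodes))
  out <- data.frame(dye_seq_id = seq_along(ucodes), code = ucodes,
                    stringsAsFactors = FALSE)
  out$peptides <- lapply(by_code, function(d) d$peptide)
  out$proteins <- lapply(by_code, function(d) d$protein)
  rownames(out) <- NULL
  attr(out, "scheme") <- scheme
  attr(out, "n_channels") <- length(scheme$channels)
  attr(out, "peptide_map") <- unique(pairs[c("peptide", "protein")])
  class(out) <- c("dye_seq_set", "data.frame")
  out
}

#' Merge dye sequences with identical codes
#'
#' Low-level counterpart of the merge performed by [make_dye_seqs()]: entries
#' sharing a code are collapsed and their source lists concatenated (total
#' source count is conserved).
#'
#' @param codes Character vector of dye-seq codes.
#' @param peptides,proteins Parallel character vectors of source provenance.
#' @return Data.frame with unique `code` plus list-columns `peptides`,
#'   `proteins`.
#' @export
merge_dye_seqs <- function(codes, peptides = codes, proteins = rep("", length(codes))) {
  stopifnot(length(codes) == length(peptides), length(codes) == length(proteins))
  ucodes <- sort(unique(codes))
  f <- factor(codes, ucodes)
  out <- data.frame(dye_seq_id = seq_along(ucodes), code = ucodes,
                    stringsAsFactors = FALSE)
  out$peptides <- split(peptides, f)
  out$proteins <- split(proteins, f)
  rownames(out) <- NULL
  out
}

#' @export
print.dye_seq_set <- function(x, ...) {
  cat("<dye_seq_set>", nrow(x), "unique dye sequences,",
      attr(x, "n_channels"), "channels\n")
  n <- min(nrow(x), 6L)
  for (i in seq_len(n)) {
    cat(sprintf("  %4d  %-20s %d source(s)\n", x$dye_seq_id[i], x$code[i],
                length(x$peptides[[i]])))
  }
  if (nrow(x) > n) cat("  ...\n")
  invisible(x)
}

#' Generate a synthetic random proteome
#'
#' Draws protein sequences with residues sampled i.i.d. from average natural
#' amino-acid frequencies (UniProt-like composition) and lognormal lengths,
#' emulating a random subset of a real proteome for simulation studies.
#'
#' @param n_proteins Number of proteins.
#' @param mean_length Mean protein length in residues.
#' @param seed Optional integer seed.
#' @return Named character vector of sequences (ids `PROT1..PROTn`).
#' @export
random_proteome <- function(n_proteins = 20, mean_length = 300, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  # average composition of well-annotated proteomes
  freq <- c(A = 8.3, C = 1.4, D = 5.5, E = 6.7, F = 3.9, G = 7.1, H = 2.3,
            I = 5.9, K = 5.8, L = 9.7, M = 2.4, N = 4.1, P = 4.7, Q = 3.9,
            R = 5.5, S = 6.6, T = 5.4, V = 6.9, W = 1.1, Y = 2.9)[aa]
  sdlog <- 0.35
  lens <- pmax(30L, round(stats::rlnorm(n_proteins,
                                        log(mean_length) - sdlog^2 / 2, sdlog)))
  seqs <- vapply(lens, function(L) {
    paste(sample(aa, L, replace = TRUE, prob = freq), collapse = "")
  }, character(1))
  names(seqs) <- paste0("PROT", seq_len(n_proteins))
  seqs
}
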