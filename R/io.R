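#' Read a protein FASTA file
#'
#' Ids are taken from the header up to the first whitespace; sequences are
#' uppercased, wrapped lines concatenated, and `'*'` stop characters
#' stripped. Duplicate ids and empty files are rejected.
#'
#' @param path FASTA file path.
#' @return Named character vector of protein sequences.
#' @export
read_fasta_proteome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA record with empty id in '", path, "'")
  if (anyDuplicated(ids)) {
    stop("duplicate protein ids in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- gsub("\\*", "", toupper(as.character(set)))
  if (any(!nzchar(seqs))) stop("empty sequence in '", path, "'")
  stats::setNames(seqs, ids)
}

#' Write a FASTA file
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Write / read a dye-sequence reference TSV
#'
#' Columns: `dye_seq_id`, `code`, `peptides`, `proteins`; the last two are
#' comma-separated parallel lists, one element per (peptide, protein) source
#' pair, so provenance pairing survives the round trip.
#'
#' @param dye_seqs A `dye_seq_set`.
#' @param path File path.
#' @param scheme Scheme to re-attach on read (optional).
#' @return `path` / a `dye_seq_set`.
#' @export
write_dye_seqs <- function(dye_seqs, path) {
  df <- data.frame(
    dye_seq_id = dye_seqs$dye_seq_id,
    code = dye_seqs$code,
    peptides = vapply(dye_seqs$peptides, paste, character(1), collapse = ","),
    proteins = vapply(dye_seqs$proteins, paste, character(1), collapse = ","))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dye_seqs
#' @export
read_dye_seqs <- function(path, scheme = NULL) {
  df <- read.delim(path, colClasses = c("integer", "character", "character",
                                        "character"))
  if (!identical(names(df), c("dye_seq_id", "code", "peptides", "proteins"))) {
    stop("unexpected dye-seq TSV header in '", path, "'")
  }
  out <- df[c("dye_seq_id", "code")]
  out$peptides <- strsplit(df$peptides, ",", fixed = TRUE)
  out$proteins <- strsplit(df$proteins, ",", fixed = TRUE)
  nch <- max(unlist(lapply(out$code, function(cd) {
    m <- match(strsplit(cd, "")[[1]], channel_chars)
    max(m, 1L, na.rm = TRUE)
  })))
  if (!is.null(scheme)) nch <- max(nch, length(scheme$channels))
  attr(out, "scheme") <- scheme
  attr(out, "n_channels") <- nch
  attr(out, "peptide_map") <- unique(data.frame(
    peptide = unlist(out$peptides), protein = unlist(out$proteins)))
  class(out) <- c("dye_seq_set", "data.frame")
  out
}

#' Write / read a deduplicated dye-track training set TSV
#'
#' Line 1 is the header `T <tab> C <tab> n_entries`; each entry line holds
#' the comma-joined flattened counts (time-major), the multiplicity, and the
#' comma-joined `dye_seq_id:count` production pairs. Round trips are
#' bit-exact.
#'
#' @param tracks A `dye_track_set`.
#' @param path File path.
#' @return `path` / a `dye_track_set`.
#' @export
write_dye_tracks <- function(tracks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(tracks$T, tracks$C, nrow(tracks$counts), sep = "\t"), con)
  if (nrow(tracks$counts) == 0L) return(invisible(path))
  counts_str <- apply(tracks$counts, 1, paste, collapse = ",")
  votes_by_entry <- split(paste0(tracks$votes$dye_seq_id, ":",
                                 tracks$votes$count),
                          factor(tracks$votes$entry,
                                 seq_len(nrow(tracks$counts))))
  votes_str <- vapply(votes_by_entry, paste, character(1), collapse = ",")
  writeLines(paste(counts_str, tracks$multiplicity, votes_str, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_dye_tracks
#' @export
read_dye_tracks <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], "\t")[[1]])
  if (length(hdr) != 3L || any(is.na(hdr))) {
    stop("bad dye-track header in '", path, "'")
  }
  Tn <- hdr[1]; C <- hdr[2]; ne <- hdr[3]
  if (length(lines) != ne + 1L) stop("entry count mismatch in '", path, "'")
  if (ne == 0L) {
    return(structure(list(T = Tn, C = C,
                          counts = matrix(integer(0), 0, Tn * C),
                          multiplicity = integer(0),
                          votes = data.frame(entry = integer(0),
                                             dye_seq_id = integer(0),
                                             count = integer(0)),
                          n_discarded = NA_integer_),
                     class = "dye_track_set"))
  }
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  counts <- do.call(rbind, lapply(parts, function(p) {
    as.integer(strsplit(p[1], ",", fixed = TRUE)[[1]])
  }))
  if (ncol(counts) != Tn * C) stop("count shape mismatch in '", path, "'")
  mult <- vapply(parts, function(p) as.integer(p[2]), integer(1))
  votes <- do.call(rbind, lapply(seq_along(parts), function(i) {
    kv <- strsplit(strsplit(parts[[i]][3], ",", fixed = TRUE)[[1]], ":",
                   fixed = TRUE)
    data.frame(entry = i,
               dye_seq_id = vapply(kv, function(z) as.integer(z[1]), integer(1)),
               count = vapply(kv, function(z) as.integer(z[2]), integer(1)))
  }))
  structure(list(T = Tn, C = C, counts = counts, multiplicity = mult,
                 votes = votes, n_discarded = NA_integer_),
            class = "dye_track_set")
}

#' Write / read a raw-read TSV
#'
#' Line 1 is `T <tab> C <tab> n_reads`; each read line holds the comma-joined
#' flattened intensities (time-major, 17 significant digits so doubles round
#' trip bit-exactly) and, when truth labels are present, the generating
#' `dye_seq_id`, peptide and protein.
#'
#' @param reads A `raw_read_set`.
#' @param path File path.
#' @return `path` / a `raw_read_set`.
#' @export
write_raw_reads <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(reads$T, reads$C, nrow(reads$y), sep = "\t"), con)
  y_str <- apply(reads$y, 1, function(r) paste(fmt17(r), collapse = ","))
  if (!is.null(reads$truth)) {
    writeLines(paste(y_str, reads$truth, reads$truth_peptide,
                     reads$truth_protein, sep = "\t"), con)
  } else if (nrow(reads$y) > 0L) {
    writeLines(y_str, con)
  }
  invisible(path)
}

#' @rdname write_raw_reads
#' @export
read_raw_reads <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], "\t")[[1]])
  if (length(hdr) != 3L || any(is.na(hdr))) {
    stop("bad raw-read header in '", path, "'")
  }
  Tn <- hdr[1]; C <- hdr[2]; nr <- hdr[3]
  if (length(lines) != nr + 1L) stop("read count mismatch in '", path, "'")
  out <- list(T = Tn, C = C, y = matrix(numeric(0), 0, Tn * C),
              truth = NULL, truth_peptide = NULL, truth_protein = NULL)
  if (nr > 0L) {
    parts <- strsplit(lines[-1], "\t", fixed = TRUE)
    out$y <- do.call(rbind, lapply(parts, function(p) {
      as.numeric(strsplit(p[1], ",", fixed = TRUE)[[1]])
    }))
    if (ncol(out$y) != Tn * C) stop("read shape mismatch in '", path, "'")
    if (length(parts[[1]]) >= 4L) {
      out$truth <- vapply(parts, function(p) as.integer(p[2]), integer(1))
      out$truth_peptide <- vapply(parts, function(p) p[3], character(1))
      out$truth_protein <- vapply(parts, function(p) p[4], character(1))
    }
  }
  structure(out, class = "raw_read_set")
}

#' Write / read a peptide-read match (PRM) TSV
#'
#' Columns: `read`, `rank`, `dye_seq_id`, `score` (17 significant digits).
#'
#' @param prms PRM data.frame.
#' @param path File path.
#' @return `path` / a data.frame.
#' @export
write_prms <- function(prms, path) {
  df <- prms
  df$score <- fmt17(df$score)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_prms
#' @export
read_prms <- function(path) {
  df <- read.delim(path, colClasses = c(read = "integer", rank = "integer",
                                        dye_seq_id = "integer",
                                        score = "numeric"))
  if (!all(c("read", "rank", "dye_seq_id", "score") %in% names(df))) {
    stop("unexpected PRM TSV header in '", path, "'")
  }
  df
}

#' Run configuration round trip
#'
#' A run configuration bundles the label scheme, sequencing parameters,
#' classifier settings, seed and file paths, and round-trips through a YAML
#' file bit-exactly (floats written with 17 significant digits).
#'
#' @param config Named list with elements `scheme` (`protease`, `channels`
#'   as strings), `params` (arguments to [seq_params()]), `classifier`
#'   (`mode` plus settings), `seed`, `paths`.
#' @param path YAML file path.
#' @return `path` / the configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 17L)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  yaml::read_yaml(path)
}

config_scheme <- function(config) {
  make_label_scheme(config$scheme$protease,
                    unlist(config$scheme$channels))
}

config_params <- function(config, n_channels) {
  do.call(seq_params, c(config$params, list(n_channels = n_channels)))
}
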