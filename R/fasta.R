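#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a tibble of protein sequences. Record ids are
#' taken from the header up to the first whitespace and sequences are
#' uppercased. Letters outside the standard 20-letter alphabet (ambiguity
#' codes B/J/O/U/X/Z, stops, gaps) are handled according to `ambiguous`:
#' either silently removed with a single summarising warning, or rejected.
#'
#' @param path Path to a FASTA file.
#' @param ambiguous Policy for non-standard residue letters: `"strip"`
#'   (default) removes them with a warning; `"error"` aborts naming the
#'   offending record.
#' @return A tibble with columns `id`, `seq` and `length`, one row per
#'   record in file order.
#' @export
read_fasta <- function(path, ambiguous = c("strip", "error")) {
  ambiguous <- match.arg(ambiguous)
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    abort(paste0("FASTA file contains no records: ", path))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  names(seqs) <- NULL
  sanitized <- sanitize_sequences(seqs, ids, ambiguous = ambiguous)
  tibble(id = ids, seq = sanitized, length = nchar(sanitized))
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences A tibble with columns `id` and `seq` (as returned by
#'   [read_fasta()] or [generate_sequences()]).
#' @param path Output file path.
#' @param width Line-wrap width for the sequence body.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  stopifnot(all(c("id", "seq") %in% names(sequences)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(sequences))) {
    writeLines(paste0(">", sequences$id[i]), con)
    s <- sequences$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

sanitize_sequences <- function(seqs, ids, ambiguous = "strip") {
  bad_pattern <- paste0("[^", paste(AA_ALPHABET, collapse = ""), "]")
  n_bad <- vapply(seqs, function(s) {
    sum(gregexpr(bad_pattern, s)[[1]] > 0L)
  }, integer(1), USE.NAMES = FALSE)
  if (any(n_bad > 0L)) {
    offenders <- ids[n_bad > 0L]
    if (ambiguous == "error") {
      abort(paste0(
        "Non-standard residue letters in record(s): ",
        paste(offenders, collapse = ", ")
      ))
    }
    warn(paste0(
      sum(n_bad), " non-standard residue letter(s) stripped from ",
      length(offenders), " record(s): ",
      paste(head(offenders, 5L), collapse = ", ")
    ))
    seqs <- gsub(bad_pattern, "", seqs)
  }
  empty <- !nzchar(seqs)
  if (any(empty)) {
    abort(paste0(
      "Empty sequence for record(s): ",
      paste(ids[empty], collapse = ", ")
    ))
  }
  seqs
}

## Split a sequence string into a character vector of residues.
residue_vector <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]
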