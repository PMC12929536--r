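#' Build an environment-by-amino-acid substitution matrix
#'
#' Derives log-odds scores from environment/amino-acid co-occurrence in a
#' database of encoded profiles: with pseudocounted joint frequencies
#' P(e, a) and marginals P(e), P(a),
#' `score[e, a] = log2( P(e, a) / (P(e) P(a)) )`.
#' The expected score under independence is non-positive, the standard
#' requirement for a local-alignment scoring system.
#'
#' @param encoded An `encoded_profile` tibble (rows may span many proteins)
#'   or a list of them; must carry `residue` and `env_<state>` columns.
#' @param state `"native"` or `"denatured"`.
#' @param pseudocount Positive smoothing count added to every (e, a) cell.
#' @return A `substitution_matrix` object: 8 x 20 score matrix (rows are
#'   environment indices 0-7, columns the amino acids in alphabetical
#'   one-letter order) plus the environment and amino-acid marginal
#'   frequencies of the database, used later for null-model calibration.
#' @export
build_substitution_matrix <- function(encoded, state = c("native", "denatured"),
                                      pseudocount = 1.0) {
  state <- match.arg(state)
  if (pseudocount <= 0) abort("pseudocount must be > 0")
  encoded <- bind_profiles(encoded)
  if (nrow(encoded) == 0L) abort("Encoded profile database is empty")
  env <- factor(encoded[[paste0("env_", state)]], levels = 0:7)
  aa <- factor(encoded$residue, levels = AA_ALPHABET)
  counts <- table(env, aa)
  smoothed <- counts + pseudocount
  P <- smoothed / sum(smoothed)
  Pe <- rowSums(P)
  Pa <- colSums(P)
  scores <- matrix(log2(as.matrix(P) / outer(Pe, Pa)), nrow = 8L, ncol = 20L,
                   dimnames = list(env = as.character(0:7), aa = AA_ALPHABET))
  structure(
    list(
      state = state,
      scores = scores,
      env_freq = as.numeric(Pe),
      aa_freq = as.numeric(Pa),
      pseudocount = pseudocount,
      n_residues = nrow(encoded)
    ),
    class = "substitution_matrix"
  )
}

#' @export
print.substitution_matrix <- function(x, ...) {
  cat("Environment x amino-acid substitution matrix (", x$state, " state)\n",
      sep = "")
  cat("  derived from", x$n_residues, "residues; score range",
      format(round(range(x$scores), 2)), "\n")
  invisible(x)
}

#' Read / write a substitution matrix TSV
#'
#' 8 rows (environments 0-7) x 20 amino-acid columns in alphabetical
#' one-letter order; the state, marginal frequencies and pseudocount are
#' carried in `#`-prefixed header comments so the file round-trips.
#'
#' @param matrix A `substitution_matrix`.
#' @param path File path.
#' @export
write_substitution_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "substitution_matrix"))
  hdr <- c(
    paste0("# state: ", matrix$state),
    paste0("# pseudocount: ", format(matrix$pseudocount, digits = 17)),
    paste0("# n_residues: ", matrix$n_residues),
    paste0("# env_freq: ", paste(format(matrix$env_freq, digits = 17),
                                 collapse = " ")),
    paste0("# aa_freq: ", paste(format(matrix$aa_freq, digits = 17),
                                collapse = " "))
  )
  writeLines(hdr, path)
  tbl <- as_tibble(matrix$scores, .name_repair = "minimal")
  tbl <- dplyr::bind_cols(tibble(env = 0:7), tbl)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_substitution_matrix
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  field <- function(key) sub(paste0("^#\\s*", key, ":\\s*"), "",
                             grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)[1])
  tbl <- readr::read_tsv(I(lines[!startsWith(lines, "#")]),
                         show_col_types = FALSE, progress = FALSE)
  scores <- as.matrix(tbl[, AA_ALPHABET])
  dimnames(scores) <- list(env = as.character(0:7), aa = AA_ALPHABET)
  structure(
    list(
      state = field("state"),
      scores = scores,
      env_freq = as.numeric(strsplit(field("env_freq"), "\\s+")[[1]]),
      aa_freq = as.numeric(strsplit(field("aa_freq"), "\\s+")[[1]]),
      pseudocount = as.numeric(field("pseudocount")),
      n_residues = as.integer(field("n_residues"))
    ),
    class = "substitution_matrix"
  )
}
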