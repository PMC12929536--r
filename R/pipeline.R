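#' Combine native and denatured chip Z-scores
#'
#' Adds `z_sum = z_native + z_denatured` to a chip measurement table. When
#' the denatured measurement is missing (as for an antibody whose denatured
#' chip was unavailable), the native value is substituted in its place
#' (`z_sum = 2 z_native`) and the row is flagged.
#'
#' @param chip A tibble with columns `protein_id`, `z_native` and
#'   `z_denatured` (`NA` = missing).
#' @return The input with added columns `z_sum` and `substituted`.
#' @export
combine_z <- function(chip) {
  stopifnot(all(c("protein_id", "z_native", "z_denatured") %in% names(chip)))
  if (anyNA(chip$z_native)) {
    abort(paste0(
      "Missing native Z-score for: ",
      paste(chip$protein_id[is.na(chip$z_native)], collapse = ", ")
    ))
  }
  substituted <- is.na(chip$z_denatured)
  if (any(substituted)) {
    inform(paste0("Substituted native Z for missing denatured Z in ",
                  sum(substituted), " row(s)"))
  }
  dplyr::mutate(
    chip,
    substituted = substituted,
    z_sum = .data$z_native +
      ifelse(substituted, .data$z_native, .data$z_denatured)
  )
}

#' Correlate chip binding with a computed similarity measure
#'
#' Pearson correlation of a pair table's `y` column (summed chip Z-score by
#' default) against a chosen x variable: the eTFR significance `S`, its
#' FVC-weighted form `S_weighted`, or the sequence-identity control
#' `identity_pct`. The two-sided p-value comes from the t-distribution with
#' n - 2 degrees of freedom; the least-squares slope and intercept are
#' reported alongside. Rows with a missing x are dropped with a message.
#'
#' @param records A tibble of pair records (e.g. from
#'   [read_pair_table()]).
#' @param x Name of the x column: `"S"`, `"S_weighted"` or
#'   `"identity_pct"`.
#' @param y Name of the y column (default `"z_sum"`).
#' @return An `emm_correlation` object; see [tidy()] and [glance()]
#'   methods.
#' @export
correlate_pairs <- function(records, x = c("S", "S_weighted", "identity_pct"),
                            y = "z_sum") {
  x <- match.arg(x)
  stopifnot(all(c(x, y) %in% names(records)))
  keep <- !is.na(records[[x]]) & !is.na(records[[y]])
  if (any(!keep)) {
    inform(paste0(sum(!keep), " record(s) with missing ", x, " or ", y,
                  " dropped"))
  }
  xs <- records[[x]][keep]
  ys <- records[[y]][keep]
  n <- length(xs)
  if (n < 3L) abort("At least 3 complete records are required")
  if (sd(xs) == 0 || sd(ys) == 0) {
    abort("Zero variance in x or y; correlation undefined")
  }
  r <- min(max(cor(xs, ys), -1), 1)
  tstat <- if (abs(r) == 1) sign(r) * Inf else r * sqrt((n - 2) / (1 - r^2))
  p <- max(2 * pt(-abs(tstat), df = n - 2), 1e-300)
  slope <- r * sd(ys) / sd(xs)
  intercept <- mean(ys) - slope * mean(xs)
  structure(
    list(
      x_field = x, y_field = y, n = n,
      r = r, r_squared = r^2, p_value = p,
      slope = slope, intercept = intercept,
      statistic = tstat,
      data = tibble(x = xs, y = ys)
    ),
    class = "emm_correlation"
  )
}

#' @export
print.emm_correlation <- function(x, ...) {
  cat("Correlation of", x$y_field, "vs", x$x_field, "\n")
  cat(sprintf("  n = %d, r = %.4f, r^2 = %.4f, p = %.3g\n",
              x$n, x$r, x$r_squared, x$p_value))
  cat(sprintf("  fit: %s = %.4f + %.4f %s\n",
              x$y_field, x$intercept, x$slope, x$x_field))
  invisible(x)
}

#' Weight eTFR significance by the fraction of strong local matches
#'
#' Adds `S_weighted = S * f` to a pair table. The weight f in `[0, 1]` is
#' the fraction of in-register FVC windows above the similarity cutoff
#' (see [alignment_weight()]); weighting can therefore only reduce the
#' full-length significance. Missing f propagates to a missing
#' `S_weighted`.
#'
#' @param records A tibble with columns `S` and `f`.
#' @return The input with an `S_weighted` column.
#' @export
weighted_significance <- function(records) {
  stopifnot(all(c("S", "f") %in% names(records)))
  bad <- !is.na(records$f) & (records$f < 0 | records$f > 1)
  if (any(bad)) abort("f must lie in [0, 1]")
  dplyr::mutate(records, S_weighted = .data$S * .data$f)
}

#' Local sequence-identity control (Smith-Waterman, BLOSUM62)
#'
#' Optimal local alignment of two amino-acid sequences under BLOSUM62 with
#' affine gap penalties (open 11, extend 1), reporting percent identity
#' over the aligned span. This is the stringent sequence-similarity control
#' used to show that thermodynamic similarity is not driven by residue
#' identity: only the single best local match contributes. Sequence pairs
#' with no positive-scoring local path report identity 0 over a span of 0.
#'
#' @param seq_a,seq_b Sequences: character strings or one-row tibbles with
#'   `seq` (and optionally `id`).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return A one-row tibble: `identity_pct`, `score`, `span_length`,
#'   `start_a`, `end_a`, `start_b`, `end_b`.
#' @export
local_identity <- function(seq_a, seq_b, gap_open = 11, gap_extend = 1) {
  sa <- target_seq(seq_a)
  sb <- target_seq(seq_b)
  if (!nzchar(sa) || !nzchar(sb)) abort("Both sequences must be non-empty")
  mat <- get_blosum62()
  al <- Biostrings::pairwiseAlignment(
    sa, sb, type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  span <- nchar(as.character(Biostrings::pattern(al)))
  if (span == 0L || Biostrings::score(al) <= 0) {
    return(tibble(
      identity_pct = 0, score = 0, span_length = 0L,
      start_a = NA_integer_, end_a = NA_integer_,
      start_b = NA_integer_, end_b = NA_integer_
    ))
  }
  pa <- Biostrings::pattern(al)
  pb <- Biostrings::subject(al)
  tibble(
    identity_pct = Biostrings::pid(al),
    score = Biostrings::score(al),
    span_length = span,
    start_a = BiocGenerics::start(pa), end_a = BiocGenerics::end(pa),
    start_b = BiocGenerics::start(pb), end_b = BiocGenerics::end(pb)
  )
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Read chip and pair tables
#'
#' `read_chip_table()` reads a TSV with columns `protein_id`, `z_native`,
#' `z_denatured` (empty cell = missing). `read_pair_table()` reads a pair
#' table with columns `virus_id`, `human_id`, `z_sum`, `S` and optionally
#' `f`, `M`, `N`; duplicate (virus, human) pairs are an input error.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_chip_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           protein_id = readr::col_character(),
                           z_native = readr::col_double(),
                           z_denatured = readr::col_double()
                         ))
  tbl
}

#' @rdname read_chip_table
#' @export
read_pair_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("virus_id", "human_id", "z_sum", "S")
  if (!all(need %in% names(tbl))) {
    abort(paste0("Pair table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  key <- paste(tbl$virus_id, tbl$human_id)
  if (anyDuplicated(key)) {
    abort("Duplicate (virus_id, human_id) pairs in pair table")
  }
  tbl
}

#' @param pairs A pair tibble.
#' @rdname read_chip_table
#' @export
write_pair_table <- function(pairs, path) {
  readr::write_tsv(pairs, path, progress = FALSE)
  invisible(path)
}

#' Reproduce the chip-correlation analysis from a pair table
#'
#' Given a pair table carrying summed chip Z-scores, eTFR significances S
#' and FVC weights f (e.g. the study's supplementary table, or a synthetic
#' equivalent), recomputes the unweighted correlation (z_sum vs S), the
#' weighted correlation (z_sum vs S x f) and, when an `identity_pct`
#' column is present, the sequence-identity control.
#'
#' @param pairs A pair tibble or a path to a pair TSV.
#' @return A named list of `emm_correlation` objects
#'   (`unweighted`, `weighted`, and possibly `identity`).
#' @export
reproduce_chip_correlations <- function(pairs) {
  if (is.character(pairs)) pairs <- read_pair_table(pairs)
  out <- list(unweighted = correlate_pairs(pairs, x = "S"))
  if ("f" %in% names(pairs)) {
    out$weighted <- correlate_pairs(weighted_significance(pairs),
                                    x = "S_weighted")
  }
  if ("identity_pct" %in% names(pairs)) {
    out$identity <- correlate_pairs(pairs, x = "identity_pct")
  }
  out
}
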