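#' Per-residue propensity table for the surrogate thermodynamic predictor
#'
#' The thermodynamic predictor used here is a windowed-mean propensity model:
#' each of the eight descriptors ({dG, dH_ap, dH_pol, TdS_conf} for the
#' native and denatured states, kcal/mol) at residue i is the mean of the
#' per-amino-acid propensity values over a symmetric window centred at i,
#' truncated at the chain ends. The packaged default table was drawn once
#' from descriptor distributions with realistic magnitudes (see the methods
#' vignette) and is shipped as a versioned TSV; tables from other predictors
#' can be supplied through [read_propensity_table()], making the surrogate
#' replaceable.
#'
#' @return A tibble with 20 rows (column `aa`) and the eight descriptor
#'   columns, with the smoothing window width in attribute `"window"`.
#' @export
default_propensity_table <- function() {
  path <- system.file("extdata", "propensity_synthetic.tsv",
                      package = "emmtools", mustWork = TRUE)
  read_propensity_table(path)
}

#' Read / write a propensity table TSV
#'
#' The TSV has 20 rows x 9 columns (`aa` plus the eight descriptors) and a
#' header comment line `# window: <odd integer>` carrying the smoothing
#' window width.
#'
#' @param path File path.
#' @return For the reader, the propensity tibble with attribute `"window"`.
#' @export
read_propensity_table <- function(path) {
  lines <- readLines(path)
  window <- 7L
  wl <- grep("^#\\s*window:", lines, value = TRUE)
  if (length(wl) > 0L) window <- as.integer(sub("^#\\s*window:\\s*", "", wl[1]))
  tbl <- readr::read_tsv(I(lines[!startsWith(lines, "#")]),
                         show_col_types = FALSE, progress = FALSE)
  validate_propensity_table(tbl)
  attr(tbl, "window") <- window
  tbl
}

#' @param table A propensity tibble.
#' @param window Window width to record in the header (odd positive integer);
#'   defaults to the table's `"window"` attribute.
#' @rdname read_propensity_table
#' @export
write_propensity_table <- function(table, path, window = NULL) {
  window <- window %||% attr(table, "window") %||% 7L
  validate_propensity_table(table)
  writeLines(paste0("# window: ", window), path)
  readr::write_tsv(table, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

validate_propensity_table <- function(table) {
  cols <- c("aa", descriptor_cols())
  if (!all(cols %in% names(table))) {
    abort("Propensity table must have columns: aa plus the 8 descriptors")
  }
  if (!setequal(table$aa, AA_ALPHABET)) {
    abort("Propensity table must have exactly one row per standard amino acid")
  }
  vals <- as.matrix(table[, descriptor_cols()])
  if (!all(is.finite(vals))) abort("Propensity table values must be finite")
  invisible(table)
}

#' Predict a per-residue thermodynamic profile from sequence
#'
#' Applies the windowed-mean propensity model: descriptor values for each
#' residue are averaged over a symmetric window of width `window` centred on
#' the residue, truncated at chain ends (so terminal residues average over
#' shorter windows). With `window = 1` the profile is a plain per-residue
#' table lookup. Residue numbering is 1-based.
#'
#' @param seq A sequence: a single character string, or a one-row tibble with
#'   columns `id` and `seq`.
#' @param table Propensity table (default [default_propensity_table()]).
#' @param window Odd positive window width; defaults to the table's window
#'   attribute.
#' @param id Identifier used when `seq` is a bare string.
#' @return A `thermo_profile` tibble with columns `id`, `pos`, `residue`
#'   and the eight descriptor columns, one row per residue.
#' @export
predict_profile <- function(seq, table = default_propensity_table(),
                            window = NULL, id = "query") {
  if (is.data.frame(seq)) {
    stopifnot(nrow(seq) == 1L)
    id <- seq$id[[1]]
    seq <- seq$seq[[1]]
  }
  window <- window %||% attr(table, "window") %||% 7L
  if (window < 1L || window %% 2L == 0L) {
    abort("window must be an odd positive integer")
  }
  res <- residue_vector(seq)
  L <- length(res)
  if (L < 1L) abort("sequence must contain at least one residue")
  row_idx <- match(res, table$aa)
  if (anyNA(row_idx)) {
    abort(paste0(
      "Residue(s) absent from propensity table: ",
      paste(unique(res[is.na(row_idx)]), collapse = ", ")
    ))
  }
  vals <- as.matrix(table[, descriptor_cols()])[row_idx, , drop = FALSE]
  smoothed <- apply(vals, 2L, windowed_mean, window = window)
  if (L == 1L) smoothed <- matrix(smoothed, nrow = 1L,
                                  dimnames = list(NULL, descriptor_cols()))
  out <- tibble(id = id, pos = seq_len(L), residue = res)
  out <- dplyr::bind_cols(out, as_tibble(smoothed))
  class(out) <- c("thermo_profile", class(out))
  out
}

## Symmetric running mean with edge truncation, O(L) via cumulative sums.
windowed_mean <- function(x, window) {
  L <- length(x)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(L) - h, 1L)
  hi <- pmin(seq_len(L) + h, L)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Read / write thermodynamic profiles as TSV
#'
#' Long format with columns `id`, `position` (1-based), `state`
#' (native/denatured), `dG`, `dH_ap`, `dH_pol`, `TdS_conf` and optionally
#' `residue`; values round-trip exactly to 6 decimals. Files may hold
#' several proteins.
#'
#' @param path File path.
#' @return For the reader, a `thermo_profile` tibble in wide per-residue form
#'   (possibly spanning several ids).
#' @export
read_profile_tsv <- function(path) {
  long <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("id", "position", "state", DESCRIPTORS)
  if (!all(need %in% names(long))) {
    abort(paste0("Profile TSV must have columns: ", paste(need, collapse = ", ")))
  }
  has_res <- "residue" %in% names(long)
  wide <- tidyr::pivot_wider(
    long,
    id_cols = dplyr::all_of(c("id", "position", if (has_res) "residue")),
    names_from = "state",
    values_from = dplyr::all_of(DESCRIPTORS),
    names_glue = "{.value}_{state}"
  )
  wide <- dplyr::rename(wide, pos = "position")
  if (!has_res) wide$residue <- NA_character_
  wide <- dplyr::select(wide, "id", "pos", "residue",
                        dplyr::all_of(descriptor_cols()))
  wide <- dplyr::arrange(wide, .data$id, .data$pos)
  class(wide) <- c("thermo_profile", class(wide))
  wide
}

#' @param profile A `thermo_profile` tibble.
#' @rdname read_profile_tsv
#' @export
write_profile_tsv <- function(profile, path) {
  long <- tidyr::pivot_longer(
    as_tibble(profile),
    cols = dplyr::all_of(descriptor_cols()),
    names_to = c(".value", "state"),
    names_pattern = "(dG|dH_ap|dH_pol|TdS_conf)_(native|denatured)"
  )
  long <- dplyr::transmute(
    long,
    id = .data$id, position = .data$pos, residue = .data$residue,
    state = .data$state,
    dplyr::across(dplyr::all_of(DESCRIPTORS), ~ round(.x, 6L))
  )
  readr::write_tsv(long, path, progress = FALSE)
  invisible(path)
}

## L x 4 descriptor matrix for one state of a single-protein profile.
profile_state_matrix <- function(profile, state) {
  as.matrix(profile[, paste(DESCRIPTORS, state, sep = "_")])
}

## L x 8 descriptor matrix, native block then denatured (flattening order).
profile_full_matrix <- function(profile) {
  as.matrix(profile[, descriptor_cols()])
}
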