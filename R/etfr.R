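#' Score one gapless register of an encoded profile against a sequence
#'
#' A register places the shorter member fully inside the longer one at a
#' 0-based `offset` (0 <= offset <= |Lq - Lt|). The raw score is the sum of
#' substitution-matrix entries over every aligned (environment, amino acid)
#' pair.
#'
#' @param query An `encoded_profile` tibble for a single protein.
#' @param target Target amino-acid sequence: a character string or a one-row
#'   tibble with a `seq` column.
#' @param offset 0-based register offset of the shorter member within the
#'   longer.
#' @param matrix A `substitution_matrix`.
#' @param state `"native"` or `"denatured"` (must match a `env_<state>`
#'   column of `query`; defaults to the matrix's state).
#' @return The raw register score (a single number).
#' @export
score_register <- function(query, target, offset, matrix,
                           state = matrix$state) {
  stopifnot(inherits(matrix, "substitution_matrix"))
  env <- query[[paste0("env_", state)]]
  aa_idx <- aa_index(target_seq(target))
  n_reg <- abs(length(env) - length(aa_idx)) + 1L
  if (offset < 0L || offset >= n_reg) {
    abort(paste0("offset must lie in [0, ", n_reg - 1L, "]"))
  }
  score_all_registers(env, aa_idx, matrix$scores)[offset + 1L]
}

## Raw scores of all full-containment registers. env: integers 0-7;
## aa_idx: integers 1-20. Returns |len difference| + 1 scores, offset order.
score_all_registers <- function(env, aa_idx, scores) {
  m <- length(env)
  n <- length(aa_idx)
  Y <- scores[env + 1L, aa_idx, drop = FALSE]
  if (m <= n) {
    base <- seq_len(m) + (seq_len(m) - 1L) * m
    vapply(0:(n - m), function(o) sum(Y[base + o * m]), numeric(1))
  } else {
    base <- seq_len(n) + (seq_len(n) - 1L) * m
    vapply(0:(m - n), function(o) sum(Y[base + o]), numeric(1))
  }
}

#' Align a thermodynamic profile to an amino-acid sequence (eTFR)
#'
#' Evaluates every full-containment gapless register of the query profile
#' against the target sequence, scoring each register in both the native
#' and denatured states, converting raw scores to Gumbel p-values, and
#' combining them as `S = -log10(p_native) - log10(p_denatured)`. The
#' register maximising S is returned (ties broken by lowest offset).
#'
#' @param query A `thermo_profile` (encoded internally via `model`) or an
#'   already-encoded `encoded_profile` tibble for a single protein.
#' @param target Target sequence: character string or one-row tibble with
#'   `id` and `seq`.
#' @param matrices Named list with `native` and `denatured`
#'   `substitution_matrix` objects.
#' @param nulls Named list with `native` and `denatured` `null_model`
#'   objects.
#' @param model An `environment_model`, required when `query` is a raw
#'   profile.
#' @return A one-row tibble: `query`, `target`, `offset` (0-based),
#'   `raw_native`, `raw_denatured`, `p_native`, `p_denatured`, `S`.
#' @export
etfr_align <- function(query, target, matrices, nulls, model = NULL) {
  for (state in STATES) {
    if (!inherits(matrices[[state]], "substitution_matrix")) {
      abort(paste0("matrices$", state, " must be a substitution_matrix"))
    }
    if (!inherits(nulls[[state]], "null_model")) {
      abort(paste0("nulls$", state, " must be a null_model"))
    }
  }
  query <- ensure_encoded(query, model)
  tid <- if (is.data.frame(target)) target$id[[1]] else "target"
  aa_idx <- aa_index(target_seq(target))
  m <- nrow(query)
  n <- length(aa_idx)
  if (m < 1L || n < 1L) abort("Both members must be non-empty")
  raw_nat <- score_all_registers(query$env_native, aa_idx,
                                 matrices$native$scores)
  raw_den <- score_all_registers(query$env_denatured, aa_idx,
                                 matrices$denatured$scores)
  p_nat <- register_significance(raw_nat, m, n, nulls$native)
  p_den <- register_significance(raw_den, m, n, nulls$denatured)
  S <- -log10(p_nat) - log10(p_den)
  best <- which.max(S)
  tibble(
    query = query$id[[1]], target = tid, offset = best - 1L,
    raw_native = raw_nat[best], raw_denatured = raw_den[best],
    p_native = p_nat[best], p_denatured = p_den[best], S = S[best]
  )
}

#' Scan a sequence database with a thermodynamic profile query
#'
#' Runs [etfr_align()] of one query profile against every target sequence
#' and ranks the results by significance S (descending; ties broken by
#' target id). Per-target failures are skipped with a summarising warning.
#'
#' @param query As in [etfr_align()].
#' @param targets A tibble of target sequences with columns `id` and `seq`
#'   (e.g. from [read_fasta()]).
#' @inheritParams etfr_align
#' @return A tibble with one row per successfully aligned target, sorted by
#'   `S` descending.
#' @export
scan_database <- function(query, targets, matrices, nulls, model = NULL) {
  if (nrow(targets) == 0L) abort("Target database is empty")
  query <- ensure_encoded(query, model)
  n_failed <- 0L
  rows <- purrr::map(seq_len(nrow(targets)), function(i) {
    tryCatch(
      etfr_align(query, targets[i, ], matrices, nulls),
      error = function(e) {
        n_failed <<- n_failed + 1L
        NULL
      }
    )
  })
  if (n_failed > 0L) {
    warn(paste0(n_failed, " target(s) skipped due to alignment errors"))
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, dplyr::desc(.data$S), .data$target)
}

ensure_encoded <- function(query, model) {
  if (inherits(query, "encoded_profile")) return(query)
  if (all(c("env_native", "env_denatured") %in% names(query))) return(query)
  if (is.null(model)) {
    abort("query is a raw profile; supply `model` to encode it")
  }
  assign_environments(query, model)
}

target_seq <- function(target) {
  if (is.data.frame(target)) target$seq[[1]] else target
}

aa_index <- function(seq) {
  idx <- match(residue_vector(seq), AA_ALPHABET)
  if (anyNA(idx)) abort("Target sequence contains non-standard residues")
  idx
}
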