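#' Run the full ensemble-molecular-mimicry pipeline on a fixture bundle
#'
#' End-to-end orchestration: sequences are profiled with the propensity
#' model, a thermodynamic-environment model is fitted across all profiles,
#' profiles are encoded, native and denatured substitution matrices are
#' derived, Gumbel null models are calibrated, every (virus, human) pair is
#' aligned by eTFR, FVC weights f = M/N are computed in the eTFR register,
#' chip Z-scores are summed and joined, and correlations of summed Z
#' against S, S x f and (optionally) the BLOSUM62 local-identity control
#' are reported. All stages are deterministic for a fixed `seed`.
#'
#' @param dir Fixture-bundle directory as written by
#'   [simulate_fixture_bundle()] (files `virus.fasta`, `human.fasta`,
#'   `propensity.tsv`, `pairs.tsv`, `chip.tsv`).
#' @param out_dir Output directory; results TSVs and a provenance record
#'   are written there (default: `dir`).
#' @param seed Integer seed for model fitting and null calibration.
#' @param L FVC window length (residues).
#' @param cutoff FVC strong-match cutoff for the weight f.
#' @param n_shuffles Shuffles per null-calibration grid point.
#' @param null_grid Optional fixed length grid forwarded to
#'   [calibrate_null()]; when supplied, one null model per state is shared
#'   by every query. The default (`NULL`) calibrates a null per virus
#'   query over that query's own observed pair dimensions (quantiles of
#'   ln(m n) across its partners), because the location of the
#'   best-register score depends on the length of the shorter member and a
#'   single global law cannot track queries of very different sizes.
#' @param compute_identity Also run the sequence-identity control
#'   (Smith-Waterman / BLOSUM62) for every pair.
#' @return Invisibly, a list: `pairs` (the augmented pair tibble) and
#'   `correlations` (named list of `emm_correlation` objects).
#' @export
run_emm_pipeline <- function(dir, out_dir = dir, seed = 1L, L = 20L,
                             cutoff = 0.95, n_shuffles = 300L,
                             null_grid = NULL,
                             compute_identity = TRUE) {
  paths <- file.path(dir, c("virus.fasta", "human.fasta", "propensity.tsv",
                            "pairs.tsv", "chip.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    abort(paste0("Pipeline input file(s) missing: ",
                 paste(missing, collapse = ", ")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  virus <- read_fasta(file.path(dir, "virus.fasta"))
  human <- read_fasta(file.path(dir, "human.fasta"))
  table <- read_propensity_table(file.path(dir, "propensity.tsv"))
  pairing <- readr::read_tsv(file.path(dir, "pairs.tsv"),
                             show_col_types = FALSE, progress = FALSE)
  chip <- read_chip_table(file.path(dir, "chip.tsv"))

  all_seqs <- dplyr::bind_rows(virus, human)
  profiles <- purrr::map(seq_len(nrow(all_seqs)),
                         function(i) predict_profile(all_seqs[i, ], table))
  names(profiles) <- all_seqs$id

  model <- fit_environment_model(profiles, k = 8L, seed = seed)
  encoded <- purrr::map(profiles, assign_environments, model = model)
  corpus <- dplyr::bind_rows(encoded)
  matrices <- list(
    native = build_substitution_matrix(corpus, "native"),
    denatured = build_substitution_matrix(corpus, "denatured")
  )
  calibrate_both <- function(grid, seed_base) {
    list(
      native = calibrate_null(matrices$native, length_grid = grid,
                              n_shuffles = n_shuffles, seed = seed_base),
      denatured = calibrate_null(matrices$denatured, length_grid = grid,
                                 n_shuffles = n_shuffles,
                                 seed = seed_base + 1L)
    )
  }
  if (!is.null(null_grid)) {
    shared_nulls <- calibrate_both(null_grid, seed + 1L)
    null_for <- function(vid) shared_nulls
  } else {
    per_query <- list()
    null_for <- function(vid) {
      if (is.null(per_query[[vid]])) {
        m_q <- virus$length[virus$id == vid]
        n_h <- human$length[human$id %in%
                              pairing$human_id[pairing$virus_id == vid]]
        dims <- unique(tibble(m = pmin(m_q, n_h), n = pmax(m_q, n_h)))
        dims <- dims[order(dims$m * dims$n), , drop = FALSE]
        take <- unique(round(seq(1L, nrow(dims), length.out = 4L)))
        grid <- purrr::map(take, function(i) c(dims$m[i], dims$n[i]))
        idx <- match(vid, virus$id)
        per_query[[vid]] <<- calibrate_both(grid, seed + 2L * idx)
      }
      per_query[[vid]]
    }
  }

  chip <- combine_z(chip)
  rows <- purrr::map(seq_len(nrow(pairing)), function(i) {
    vid <- pairing$virus_id[i]
    hid <- pairing$human_id[i]
    hit <- etfr_align(encoded[[vid]], human[human$id == hid, ],
                      matrices, null_for(vid))
    w <- alignment_weight(profiles[[vid]], profiles[[hid]], hit$offset,
                          L = L, cutoff = cutoff)
    row <- tibble(
      virus_id = vid, human_id = hid,
      offset = hit$offset, S = hit$S,
      f = w$f, M = w$M, N = w$N
    )
    if (compute_identity) {
      row$identity_pct <- local_identity(virus[virus$id == vid, ],
                                         human[human$id == hid, ])$identity_pct
    }
    row
  })
  pairs <- dplyr::bind_rows(rows)
  pairs <- dplyr::left_join(
    pairs,
    dplyr::select(chip, human_id = "protein_id", "z_sum"),
    by = "human_id"
  )
  pairs <- weighted_significance(pairs)

  correlations <- list(unweighted = correlate_pairs(pairs, x = "S"))
  if (any(!is.na(pairs$f))) {
    correlations$weighted <- correlate_pairs(pairs, x = "S_weighted")
  }
  if (compute_identity) {
    correlations$identity <- correlate_pairs(pairs, x = "identity_pct")
  }

  write_pair_table(pairs, file.path(out_dir, "pair_results.tsv"))
  readr::write_tsv(
    dplyr::bind_rows(purrr::map(correlations, glance), .id = "analysis"),
    file.path(out_dir, "correlations.tsv"), progress = FALSE
  )
  jsonlite::write_json(
    list(seed = seed, L = L, cutoff = cutoff, n_shuffles = n_shuffles,
         n_pairs = nrow(pairs),
         inputs = basename(paths)),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE
  )
  invisible(list(pairs = pairs, correlations = correlations))
}
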