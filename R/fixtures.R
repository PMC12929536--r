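#' Generate random protein sequences
#'
#' Residues are drawn i.i.d. from `composition`; lengths are uniform over
#' `length_range`. Defaults mirror the study design: proteins spanning
#' roughly the sizes of the viral antigens and their human binding
#' partners.
#'
#' @param n Number of sequences.
#' @param length_range Inclusive range of sequence lengths.
#' @param composition Named amino-acid frequency vector (default uniform
#'   over the 20 standard residues); normalised internally.
#' @param seed Integer seed; identical seeds give identical output.
#' @param prefix Id prefix.
#' @return A tibble with columns `id`, `seq`, `length`.
#' @export
generate_sequences <- function(n, length_range = c(100L, 1200L),
                               composition = NULL, seed = 1L,
                               prefix = "prot") {
  composition <- normalize_composition(composition)
  withr::with_seed(seed, {
    lens <- sample.int(length_range[2] - length_range[1] + 1L, n,
                       replace = TRUE) + length_range[1] - 1L
    seqs <- vapply(lens, function(L) {
      paste(sample(AA_ALPHABET, L, replace = TRUE, prob = composition),
            collapse = "")
    }, character(1))
    tibble(id = sprintf("%s%03d", prefix, seq_len(n)), seq = seqs,
           length = lens)
  })
}

normalize_composition <- function(composition) {
  if (is.null(composition)) {
    composition <- setNames(rep(1 / 20, 20L), AA_ALPHABET)
  }
  if (!is.null(names(composition))) {
    composition <- composition[AA_ALPHABET]
  }
  if (length(composition) != 20L || anyNA(composition) ||
      any(composition < 0)) {
    abort("composition must be a non-negative frequency vector over the 20 amino acids")
  }
  composition / sum(composition)
}

#' Generate a random propensity table
#'
#' Draws one propensity value per amino acid and descriptor from normal
#' distributions with realistic per-residue magnitudes (kcal/mol): free
#' energies near 1-2, apolar/polar enthalpies of a few kcal/mol with
#' opposite signs, small conformational entropy terms; denatured-state
#' values are centred near zero. Used as the surrogate predictor's
#' parameter set in tests; the packaged default table was produced by this
#' generator at a recorded seed.
#'
#' @param seed Integer seed.
#' @param window Smoothing window width recorded with the table.
#' @return A propensity tibble (20 rows x 8 descriptors) with attribute
#'   `"window"`.
#' @export
random_propensity_table <- function(seed = 1L, window = 7L) {
  means <- c(
    dG_native = 1.5, dH_ap_native = -3.0, dH_pol_native = 4.0,
    TdS_conf_native = 1.2,
    dG_denatured = 0.2, dH_ap_denatured = -0.8, dH_pol_denatured = 1.0,
    TdS_conf_denatured = 2.0
  )
  sds <- c(1.0, 2.0, 2.0, 0.8, 0.6, 1.2, 1.2, 0.7)
  withr::with_seed(seed, {
    vals <- vapply(seq_along(means),
                   function(j) rnorm(20L, means[j], sds[j]),
                   numeric(20L))
    colnames(vals) <- descriptor_cols()
    tbl <- dplyr::bind_cols(tibble(aa = AA_ALPHABET), as_tibble(vals))
    attr(tbl, "window") <- as.integer(window)
    tbl
  })
}

#' Generate descriptor training data from separated Gaussian blobs
#'
#' Emits a pseudo-profile whose per-residue descriptor vectors are drawn
#' from `k` well-separated Gaussian blobs per state, for testing
#' environment-model recovery. Blob centres are placed at random corners of
#' a hypercube with side `separation` (in raw descriptor units) and jittered.
#'
#' @param n_per_blob Points drawn per blob.
#' @param k Number of blobs per state.
#' @param separation Distance scale between blob centres.
#' @param noise_sd Within-blob standard deviation.
#' @param seed Integer seed.
#' @return A list: `profile` (a `thermo_profile`-shaped tibble) and
#'   `centers` (per-state k x 4 matrices of true blob means).
#' @export
generate_blob_profiles <- function(n_per_blob = 100L, k = 8L,
                                   separation = 10, noise_sd = 0.5,
                                   seed = 1L) {
  withr::with_seed(seed, {
    n <- n_per_blob * k
    out <- tibble(
      id = "blobs", pos = seq_len(n),
      residue = sample(AA_ALPHABET, n, replace = TRUE)
    )
    centers <- list()
    for (state in STATES) {
      ctr <- matrix(runif(k * 4L, -1, 1) * separation, k, 4L)
      ## nudge apart any close pair of centres
      repeat {
        d <- as.matrix(stats::dist(ctr))
        diag(d) <- Inf
        if (min(d) > 6 * noise_sd) break
        ctr <- ctr + matrix(runif(k * 4L, -1, 1) * separation / 2, k, 4L)
      }
      colnames(ctr) <- DESCRIPTORS
      centers[[state]] <- ctr
      lab <- rep(seq_len(k), each = n_per_blob)
      pts <- ctr[lab, ] + matrix(rnorm(n * 4L, 0, noise_sd), n, 4L)
      colnames(pts) <- paste(DESCRIPTORS, state, sep = "_")
      out <- dplyr::bind_cols(out, as_tibble(pts))
    }
    class(out) <- c("thermo_profile", class(out))
    list(profile = out, centers = centers)
  })
}

#' Plant a copied thermodynamic fragment between two profiles
#'
#' Copies a block of `length` residues of descriptor values from profile
#' `a` (starting at `start_a`) into profile `b` (at `start_b`), leaving
#' everything else untouched. The planted register then has FVC cosine 1
#' and serves as a synthetic "known epitope". A zero-length plant returns
#' `b` unchanged.
#'
#' @param a,b Single-protein `thermo_profile` tibbles.
#' @param length Number of residues to copy.
#' @param start_a,start_b 1-based block starts in `a` and `b`.
#' @return The modified copy of `b`.
#' @export
plant_fragment <- function(a, b, length, start_a, start_b) {
  if (length == 0L) return(b)
  if (length < 0L || start_a < 1L || start_b < 1L ||
      start_a + length - 1L > nrow(a) || start_b + length - 1L > nrow(b)) {
    abort("Planted fragment out of range")
  }
  cols <- descriptor_cols()
  b[start_b:(start_b + length - 1L), cols] <-
    a[start_a:(start_a + length - 1L), cols]
  b
}

#' Generate a chip/pair table with planted significance-affinity dependence
#'
#' Emulates the statistical structure of the proteome-chip analysis: summed
#' Z-scores depend linearly on the eTFR significance with Gaussian residual
#' scatter, `z_sum_i = alpha * S_i + eps_i`, `eps ~ N(0, sigma^2)`. With
#' `alpha = 0` the planted correlation is null.
#'
#' @param S Vector of pair significances (one per virus-human pair).
#' @param alpha Planted slope.
#' @param sigma Residual standard deviation (> 0).
#' @param seed Integer seed.
#' @param virus_id,human_id Optional id vectors (defaults generated).
#' @return A pair tibble: `virus_id`, `human_id`, `z_sum`, `S`.
#' @export
generate_chip_table <- function(S, alpha, sigma, seed = 1L,
                                virus_id = NULL, human_id = NULL) {
  if (sigma <= 0) abort("sigma must be > 0")
  n <- length(S)
  virus_id <- virus_id %||% sprintf("virus%02d", rep(seq_len(ceiling(n / 10)),
                                                     each = 10L)[seq_len(n)])
  human_id <- human_id %||% sprintf("human%03d", seq_len(n))
  withr::with_seed(seed, {
    tibble(
      virus_id = virus_id, human_id = human_id,
      z_sum = alpha * S + rnorm(n, 0, sigma),
      S = S
    )
  })
}

#' Residual noise giving a planted population r-squared
#'
#' For the linear model `z = alpha S + eps`, the population coefficient of
#' determination is `r2 = alpha^2 Var(S) / (alpha^2 Var(S) + sigma^2)`;
#' this helper solves for the `sigma` that plants a requested `r2` for a
#' fixed design vector `S` (population variance, i.e. divisor n).
#'
#' @param S Design vector of significances.
#' @param alpha Planted slope.
#' @param r_squared Target population r-squared, in (0, 1).
#' @return The residual SD `sigma`.
#' @export
noise_for_r_squared <- function(S, alpha, r_squared) {
  if (r_squared <= 0 || r_squared >= 1) abort("r_squared must be in (0, 1)")
  v <- mean((S - mean(S))^2)
  sqrt(alpha^2 * v * (1 - r_squared) / r_squared)
}

#' Write a complete synthetic fixture bundle
#'
#' Emits, into `dir`: virus and human FASTA files, a propensity table, a
#' chip Z-score table, a (virus, human) pairing table and a manifest
#' recording the seed and parameters. Defaults mirror the study design
#' (7 antigens x 10 binding partners; protein lengths spanning the viral
#' antigens used). The bundle is the input of [run_emm_pipeline()].
#'
#' @param dir Output directory (created if absent).
#' @param n_virus Number of virus antigens.
#' @param n_human_per_virus Binding partners reported per antigen.
#' @param length_range Protein length range.
#' @param seed Integer seed.
#' @return `dir`, invisibly; files are written as a side effect.
#' @export
simulate_fixture_bundle <- function(dir, n_virus = 7L,
                                    n_human_per_virus = 10L,
                                    length_range = c(100L, 1200L),
                                    seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_human <- n_virus * n_human_per_virus
  virus <- generate_sequences(n_virus, length_range, seed = seed,
                              prefix = "virus")
  human <- generate_sequences(n_human, length_range, seed = seed + 1L,
                              prefix = "human")
  write_fasta(virus, file.path(dir, "virus.fasta"))
  write_fasta(human, file.path(dir, "human.fasta"))
  table <- random_propensity_table(seed = seed + 2L)
  write_propensity_table(table, file.path(dir, "propensity.tsv"))
  pairs <- tibble(
    virus_id = rep(virus$id, each = n_human_per_virus),
    human_id = human$id
  )
  readr::write_tsv(pairs, file.path(dir, "pairs.tsv"), progress = FALSE)
  chip <- withr::with_seed(seed + 3L, tibble(
    protein_id = human$id,
    z_native = rnorm(n_human, 3, 1),
    z_denatured = rnorm(n_human, 3, 1)
  ))
  readr::write_tsv(chip, file.path(dir, "chip.tsv"), progress = FALSE)
  manifest <- list(
    seed = seed, n_virus = n_virus, n_human_per_virus = n_human_per_virus,
    length_range = as.integer(length_range),
    files = c("virus.fasta", "human.fasta", "propensity.tsv", "pairs.tsv",
              "chip.tsv")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
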