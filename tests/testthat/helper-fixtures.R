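# Shared fixtures and independent oracles for the test suite.
# The "setup" corpus (sequences -> profiles -> environment model -> encoded
# profiles -> substitution matrices) is built once per session and reused.

.setup_cache <- new.env(parent = emptyenv())

test_setup <- function() {
  if (!is.null(.setup_cache$setup)) return(.setup_cache$setup)
  seqs <- generate_sequences(14, c(80, 260), seed = 42)
  table <- random_propensity_table(seed = 7)
  profiles <- lapply(seq_len(nrow(seqs)),
                     function(i) predict_profile(seqs[i, ], table))
  names(profiles) <- seqs$id
  model <- fit_environment_model(profiles, seed = 3)
  encoded <- lapply(profiles, assign_environments, model = model)
  corpus <- dplyr::bind_rows(encoded)
  matrices <- list(
    native = build_substitution_matrix(corpus, "native"),
    denatured = build_substitution_matrix(corpus, "denatured")
  )
  .setup_cache$setup <- list(
    seqs = seqs, table = table, profiles = profiles, model = model,
    encoded = encoded, corpus = corpus, matrices = matrices
  )
  .setup_cache$setup
}

test_nulls <- function() {
  if (!is.null(.setup_cache$nulls)) return(.setup_cache$nulls)
  s <- test_setup()
  grid <- list(c(80L, 240L), c(80L, 480L))
  .setup_cache$nulls <- list(
    native = calibrate_null(s$matrices$native, length_grid = grid,
                            n_shuffles = 200, seed = 11),
    denatured = calibrate_null(s$matrices$denatured, length_grid = grid,
                               n_shuffles = 200, seed = 12)
  )
  .setup_cache$nulls
}

# --- independent oracles -------------------------------------------------

# Gapless register scores by explicit double loop (no shared code with the
# implementation's banded-index trick).
oracle_register_scores <- function(env, aa_idx, scores) {
  m <- length(env)
  n <- length(aa_idx)
  if (m <= n) {
    sapply(0:(n - m), function(o) {
      tot <- 0
      for (i in seq_len(m)) tot <- tot + scores[env[i] + 1L, aa_idx[i + o]]
      tot
    })
  } else {
    sapply(0:(m - n), function(o) {
      tot <- 0
      for (j in seq_len(n)) tot <- tot + scores[env[j + o] + 1L, aa_idx[j]]
      tot
    })
  }
}

oracle_cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))

# Pearson r, t statistic and two-sided p via the covariance formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r <- sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), n - 2))
}

# Count-and-log substitution scores, written independently of the package.
oracle_submatrix <- function(env, residue, pseudocount = 1) {
  C <- matrix(0, 8, 20)
  for (i in seq_along(env)) {
    a <- match(residue[i], c("A","C","D","E","F","G","H","I","K","L",
                             "M","N","P","Q","R","S","T","V","W","Y"))
    C[env[i] + 1L, a] <- C[env[i] + 1L, a] + 1
  }
  Cs <- C + pseudocount
  P <- Cs / sum(Cs)
  out <- matrix(NA_real_, 8, 20)
  for (e in 1:8) for (a in 1:20) {
    out[e, a] <- log2(P[e, a] / (sum(P[e, ]) * sum(P[, a])))
  }
  out
}

# Exhaustive enumeration of all 2^n equally likely outcomes (p0 = 1/2).
enumerate_binom_tail <- function(k, n) {
  hits <- 0L
  for (b in 0:(2^n - 1)) {
    if (sum(as.integer(intToBits(b))[1:n]) >= k) hits <- hits + 1L
  }
  hits / 2^n
}

# A hand-specifiable substitution matrix object for scoring tests.
manual_matrix <- function(scores, state = "native") {
  dimnames(scores) <- list(env = as.character(0:7),
                           aa = c("A","C","D","E","F","G","H","I","K","L",
                                  "M","N","P","Q","R","S","T","V","W","Y"))
  structure(
    list(state = state, scores = scores,
         env_freq = rep(1 / 8, 8), aa_freq = rep(1 / 20, 20),
         pseudocount = 1, n_residues = 0L),
    class = "substitution_matrix"
  )
}

# Minimal encoded-profile tibble for a given environment string.
manual_encoded <- function(env_native, env_denatured = env_native,
                           id = "q") {
  out <- tibble::tibble(
    id = id, pos = seq_along(env_native),
    residue = rep("A", length(env_native)),
    env_native = as.integer(env_native),
    env_denatured = as.integer(env_denatured)
  )
  class(out) <- c("encoded_profile", class(out))
  out
}

random_profile <- function(L, seed, id = "p") {
  withr::with_seed(seed, {
    vals <- matrix(stats::rnorm(L * 8), L, 8)
    colnames(vals) <- c("dG_native", "dH_ap_native", "dH_pol_native",
                        "TdS_conf_native", "dG_denatured", "dH_ap_denatured",
                        "dH_pol_denatured", "TdS_conf_denatured")
    out <- dplyr::bind_cols(
      tibble::tibble(id = id, pos = seq_len(L),
                     residue = sample(c("A","C","D","E","F","G","H","I","K",
                                        "L","M","N","P","Q","R","S","T","V",
                                        "W","Y"), L, replace = TRUE)),
      tibble::as_tibble(vals)
    )
    class(out) <- c("thermo_profile", class(out))
    out
  })
}
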