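#' Calibrate the extreme-value null model for eTFR scores
#'
#' The best-register raw score of a random profile/sequence pair is treated
#' as an extreme value: for each length pair (m, n) in `length_grid`,
#' `n_shuffles` random pairs are generated (environment letters i.i.d. from
#' the database environment frequencies carried by `matrix`, residues
#' i.i.d. from `composition`), the maximum raw score over all |m - n| + 1
#' registers is recorded, and a Gumbel location/scale is fitted by the
#' method of moments. The location is then regressed on ln(m n), giving the
#' length-dependent law `mu(m, n) = a + b ln(m n)`; the scale `beta` is the
#' across-grid mean. Grid pairs should have unequal lengths so each maximum
#' is taken over many registers (the extreme-value regime).
#'
#' @param matrix A `substitution_matrix` (supplies scores and environment
#'   frequencies).
#' @param composition Amino-acid frequency vector, length 20 in alphabetical
#'   one-letter order (default: the database amino-acid frequencies stored
#'   in `matrix`). Normalised internally.
#' @param length_grid List of `c(m, n)` length pairs. The default holds the
#'   query length fixed and varies the target length: under a fixed scoring
#'   system the location of the best-register score grows with the register
#'   count (ln n) while the per-position drift scales with the query length
#'   itself, so a fixed-m grid is the design under which the
#'   `a + b ln(m n)` law holds.
#' @param n_shuffles Shuffled pairs per grid point (>= 100).
#' @param seed Integer seed.
#' @return A `null_model` object with fields `state`, `a`, `b`, `beta`, the
#'   per-grid-point fits, `n_shuffles` and `seed`.
#' @export
calibrate_null <- function(matrix,
                           composition = NULL,
                           length_grid = list(c(100L, 300L), c(100L, 500L),
                                              c(100L, 800L), c(100L, 1200L)),
                           n_shuffles = 1000L,
                           seed = 1L) {
  stopifnot(inherits(matrix, "substitution_matrix"))
  if (n_shuffles < 100L) abort("n_shuffles must be >= 100 per grid point")
  composition <- composition %||% matrix$aa_freq
  if (length(composition) != 20L || any(composition < 0)) {
    abort("composition must be a non-negative vector of length 20")
  }
  composition <- composition / sum(composition)
  env_freq <- matrix$env_freq / sum(matrix$env_freq)
  grid <- withr::with_seed(seed, {
    purrr::map_dfr(length_grid, function(mn) {
      m <- as.integer(mn[1]); n <- as.integer(mn[2])
      best <- replicate(n_shuffles, {
        env <- sample.int(8L, min(m, n), replace = TRUE, prob = env_freq) - 1L
        aa <- sample.int(20L, max(m, n), replace = TRUE, prob = composition)
        max(score_all_registers(env, aa, matrix$scores))
      })
      s <- sd(best)
      if (!is.finite(s) || s <= 0) abort("Degenerate null score distribution")
      beta_i <- s * sqrt(6) / pi
      mu_i <- mean(best) - 0.5772156649015329 * beta_i
      tibble(m = m, n = n, mu = mu_i, beta = beta_i)
    })
  })
  if (length(unique(log(grid$m * grid$n))) > 1L) {
    fit <- stats::lm(mu ~ log(m * n), data = grid)
    a <- unname(stats::coef(fit)[1])
    b <- unname(stats::coef(fit)[2])
  } else {
    ## single length product: location is a constant
    a <- mean(grid$mu)
    b <- 0
  }
  structure(
    list(
      state = matrix$state,
      a = a,
      b = b,
      beta = mean(grid$beta),
      grid = grid,
      n_shuffles = as.integer(n_shuffles),
      seed = as.integer(seed)
    ),
    class = "null_model"
  )
}

#' Convert a raw eTFR register score to a p-value
#'
#' Gumbel tail with length-dependent location:
#' `p = 1 - exp(-exp(-(raw - mu(m, n)) / beta))` with
#' `mu(m, n) = a + b ln(m n)`. p-values are floored at 1e-300 so their
#' negative logarithms stay finite.
#'
#' @param raw Raw score (vectorised).
#' @param m,n Lengths of the two aligned members.
#' @param null A `null_model`.
#' @return p-values in `[1e-300, 1]`.
#' @export
register_significance <- function(raw, m, n, null) {
  stopifnot(inherits(null, "null_model"))
  mu <- null$a + null$b * log(as.numeric(m) * as.numeric(n))
  z <- (raw - mu) / null$beta
  p <- -expm1(-exp(-z))
  pmin(pmax(p, 1e-300), 1)
}

#' @export
print.null_model <- function(x, ...) {
  cat("eTFR Gumbel null model (", x$state, " state)\n", sep = "")
  cat(sprintf("  mu(m, n) = %.4f + %.4f ln(mn); beta = %.4f\n",
              x$a, x$b, x$beta))
  cat("  calibrated with", x$n_shuffles, "shuffles per grid point, seed",
      x$seed, "\n")
  invisible(x)
}

#' Save / load a null model
#'
#' @param null A `null_model`.
#' @param path File path (JSON).
#' @export
write_null_model <- function(null, path) {
  stopifnot(inherits(null, "null_model"))
  payload <- list(
    state = null$state, a = null$a, b = null$b, beta = null$beta,
    n_shuffles = null$n_shuffles, seed = null$seed,
    grid = as.list(as.data.frame(null$grid))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_null_model
#' @export
read_null_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      state = p$state, a = p$a, b = p$b, beta = p$beta,
      grid = as_tibble(p$grid),
      n_shuffles = as.integer(p$n_shuffles), seed = as.integer(p$seed)
    ),
    class = "null_model"
  )
}
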