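#' Extract flattened fragment vectors from a thermodynamic profile
#'
#' Slides a window of `L` residues along the profile (step 1) and flattens
#' each window into an 8L-dimensional vector, residue-major: for each
#' residue in order, the four native-state descriptors
#' (dG, dH_ap, dH_pol, TdS_conf) followed by the four denatured-state
#' descriptors.
#'
#' @param profile A single-protein `thermo_profile`.
#' @param L Window length in residues (1 <= L <= protein length).
#' @return A tibble with columns `id`, `start` (1-based), `L` and a
#'   list-column `v` of numeric vectors of length 8L.
#' @export
fragment_vectors <- function(profile, L) {
  M <- fragment_matrix(profile, L)
  tibble(
    id = profile$id[[1]],
    start = seq_len(nrow(M)),
    L = as.integer(L),
    v = lapply(seq_len(nrow(M)), function(i) M[i, ])
  )
}

## (length - L + 1) x 8L matrix of flattened windows, residue-major.
fragment_matrix <- function(profile, L) {
  P <- profile_full_matrix(profile)
  n <- nrow(P)
  if (L < 1L || L > n) abort("L must satisfy 1 <= L <= protein length")
  nw <- n - L + 1L
  ## column j of the output = descriptor (j-1) %% 8 of residue (j-1) %/% 8
  out <- matrix(NA_real_, nw, 8L * L)
  for (r in seq_len(L)) {
    out[, (r - 1L) * 8L + 1:8] <- P[r:(r + nw - 1L), , drop = FALSE]
  }
  out
}

#' All-pairs windowed cosine similarity between two profiles (FVC)
#'
#' Computes the cosine similarity `u . v / (|u| |v|)` between every pair of
#' 8L-dimensional fragment vectors of the two proteins, retaining the full
#' score population as the background distribution and returning matches at
#' or above `cutoff` sorted by similarity (descending; ties by `start_a`
#' then `start_b`). Zero-norm fragments have undefined cosine; such pairs
#' are excluded and counted.
#'
#' @param a,b Single-protein `thermo_profile` tibbles.
#' @param L Window length, valid for both proteins.
#' @param cutoff Minimum cosine similarity retained in `matches`
#'   (in `[-1, 1]`; use -1 or 0 to keep everything).
#' @return An `fvc_result` object: `matches` tibble
#'   (`start_a`, `start_b`, `L`, `cosine`), `background` (an
#'   `fvc_background` with the full score vector and summary), and `meta`.
#' @export
fvc_compare <- function(a, b, L, cutoff = 0) {
  if (cutoff < -1 || cutoff > 1) abort("cutoff must lie in [-1, 1]")
  C <- cosine_matrix(fragment_matrix(a, L), fragment_matrix(b, L))
  n_undefined <- sum(is.na(C))
  if (n_undefined > 0L) {
    inform(paste0(n_undefined,
                  " window pair(s) with zero-norm fragments excluded"))
  }
  scores <- as.numeric(C)
  grid <- expand.grid(start_a = seq_len(nrow(C)), start_b = seq_len(ncol(C)))
  matches <- tibble(
    start_a = grid$start_a, start_b = grid$start_b,
    L = as.integer(L), cosine = scores
  )
  matches <- dplyr::filter(matches, !is.na(.data$cosine),
                           .data$cosine >= cutoff)
  matches <- dplyr::arrange(matches, dplyr::desc(.data$cosine),
                            .data$start_a, .data$start_b)
  background <- new_fvc_background(
    scores[!is.na(scores)],
    id_a = a$id[[1]], id_b = b$id[[1]], L = L,
    n_expected = nrow(C) * ncol(C), n_undefined = n_undefined
  )
  structure(
    list(
      matches = matches,
      background = background,
      meta = list(id_a = a$id[[1]], id_b = b$id[[1]], L = as.integer(L),
                  cutoff = cutoff, n_undefined = n_undefined)
    ),
    class = "fvc_result"
  )
}

## Row-pairwise cosine between fragment matrices; zero-norm rows give NA.
cosine_matrix <- function(Fa, Fb) {
  na <- sqrt(rowSums(Fa^2))
  nb <- sqrt(rowSums(Fb^2))
  C <- (Fa %*% t(Fb)) / outer(na, nb)
  C[!is.finite(C)] <- NA_real_
  pmin(pmax(C, -1), 1)
}

new_fvc_background <- function(scores, id_a, id_b, L, n_expected,
                               n_undefined) {
  structure(
    list(
      id_a = id_a, id_b = id_b, L = as.integer(L),
      scores = scores,
      n_expected = n_expected, n_undefined = n_undefined,
      summary = tibble(
        min = min(scores), q1 = unname(quantile(scores, 0.25)),
        mean = mean(scores), q3 = unname(quantile(scores, 0.75)),
        max = max(scores), count = length(scores)
      )
    ),
    class = "fvc_background"
  )
}

#' @export
print.fvc_result <- function(x, ...) {
  cat("FVC comparison:", x$meta$id_a, "vs", x$meta$id_b,
      "(L =", paste0(x$meta$L, ")"), "\n")
  cat("  ", nrow(x$matches), "match(es) at cosine >=", x$meta$cutoff,
      "of", x$background$n_expected, "window pairs\n")
  print(x$background$summary)
  invisible(x)
}

#' Test a published epitope register against the FVC background
#'
#' Extracts the single cosine similarity at the register of a published
#' epitope alignment (1-based starts in both proteins, window `L`) and
#' compares it with the arithmetic mean of the all-pairs background
#' distribution for the same window length.
#'
#' @param a,b Single-protein `thermo_profile` tibbles.
#' @param L Epitope alignment length (the window length).
#' @param start_a,start_b 1-based start of the published register in each
#'   protein.
#' @return An `epitope_test` tibble (one row): ids, register,
#'   `epitope_cosine`, `background_mean`, `above_average`; the full
#'   `fvc_background` rides in attribute `"background"` for plotting.
#' @export
epitope_background_test <- function(a, b, L, start_a, start_b) {
  if (start_a < 1L || start_a + L - 1L > nrow(a) ||
      start_b < 1L || start_b + L - 1L > nrow(b)) {
    abort("Epitope register out of range for these proteins")
  }
  res <- fvc_compare(a, b, L, cutoff = -1)
  hit <- dplyr::filter(res$matches, .data$start_a == !!start_a,
                       .data$start_b == !!start_b)
  if (nrow(hit) == 0L) abort("Epitope register cosine undefined (zero norm)")
  bg_mean <- res$background$summary$mean
  out <- tibble(
    id_a = a$id[[1]], id_b = b$id[[1]],
    start_a = as.integer(start_a), start_b = as.integer(start_b),
    L = as.integer(L),
    epitope_cosine = hit$cosine,
    background_mean = bg_mean,
    above_average = hit$cosine > bg_mean
  )
  attr(out, "background") <- res$background
  class(out) <- c("epitope_test", class(out))
  out
}

#' Exact binomial upper-tail probability
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`, summed exactly. Used to score how
#' surprising it is that `k` of `n` epitopes exceed their background mean
#' under a null success probability `p0`.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials.
#' @param p0 Null success probability, in (0, 1).
#' @return The upper-tail p-value.
#' @export
binomial_tail <- function(k, n, p0 = 0.5) {
  if (p0 <= 0 || p0 >= 1) abort("p0 must lie strictly in (0, 1)")
  if (k < 0L || k > n) abort("k must satisfy 0 <= k <= n")
  if (k == 0L) return(1.0)
  sum(dbinom(k:n, n, p0))
}

#' In-register FVC weight f = M/N for an eTFR alignment
#'
#' Restricts FVC to the window pairs lying in the register found by the
#' full-length eTFR alignment: window starts in the shorter protein
#' i = 1 .. N (N = shorter length - L + 1), paired with windows starting at
#' i + offset in the longer protein. Of these N cosines, M exceed `cutoff`
#' (strictly greater), and the weight is f = M/N. When the overlap is
#' shorter than `L` the weight is undefined and returned as missing.
#'
#' @param a,b Single-protein `thermo_profile` tibbles (either order; the
#'   shorter is slid inside the longer).
#' @param offset 0-based eTFR register offset of the shorter protein within
#'   the longer.
#' @param L Window length (default 20 residues).
#' @param cutoff Cosine similarity threshold (default 0.95).
#' @return A one-row tibble: `id_a`, `id_b`, `offset`, `L`, `cutoff`, `M`,
#'   `N`, `f`.
#' @export
alignment_weight <- function(a, b, offset, L = 20L, cutoff = 0.95) {
  swap <- nrow(a) > nrow(b)
  shorter <- if (swap) b else a
  longer <- if (swap) a else b
  n_reg <- nrow(longer) - nrow(shorter) + 1L
  if (offset < 0L || offset >= n_reg) {
    abort(paste0("offset must lie in [0, ", n_reg - 1L, "]"))
  }
  skeleton <- tibble(
    id_a = a$id[[1]], id_b = b$id[[1]], offset = as.integer(offset),
    L = as.integer(L), cutoff = cutoff,
    M = NA_integer_, N = NA_integer_, f = NA_real_
  )
  if (nrow(shorter) < L) {
    inform("Overlap shorter than L; weight f undefined")
    return(skeleton)
  }
  Fs <- fragment_matrix(shorter, L)
  Fl <- fragment_matrix(longer, L)
  N <- nrow(Fs)
  idx_l <- seq_len(N) + offset
  num <- rowSums(Fs * Fl[idx_l, , drop = FALSE])
  den <- sqrt(rowSums(Fs^2)) * sqrt(rowSums(Fl[idx_l, , drop = FALSE]^2))
  cosines <- pmin(pmax(num / den, -1), 1)
  n_undef <- sum(!is.finite(cosines))
  if (n_undef > 0L) {
    inform(paste0(n_undef, " in-register window(s) with zero norm excluded"))
  }
  keep <- is.finite(cosines)
  M <- sum(cosines[keep] > cutoff)
  skeleton$M <- as.integer(M)
  skeleton$N <- as.integer(N)
  skeleton$f <- M / N
  skeleton
}
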