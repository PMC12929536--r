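#' Tidy an EMM correlation fit
#'
#' Broom-style one-row-per-term summary of the least-squares fit behind an
#' [correlate_pairs()] result.
#'
#' @param x An `emm_correlation` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @method tidy emm_correlation
#' @export
tidy.emm_correlation <- function(x, ...) {
  d <- x$data
  n <- x$n
  sxx <- sum((d$x - mean(d$x))^2)
  resid <- d$y - (x$intercept + x$slope * d$x)
  s2 <- sum(resid^2) / (n - 2)
  se_slope <- sqrt(s2 / sxx)
  se_int <- sqrt(s2 * (1 / n + mean(d$x)^2 / sxx))
  est <- c(x$intercept, x$slope)
  se <- c(se_int, se_slope)
  stat <- est / se
  tibble(
    term = c("(Intercept)", x$x_field),
    estimate = est,
    std.error = se,
    statistic = stat,
    p.value = 2 * pt(-abs(stat), df = n - 2)
  )
}

#' Glance at an EMM correlation fit
#'
#' @param x An `emm_correlation` object.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `r`, `r.squared`, `statistic`, `p.value`,
#'   `slope`, `intercept`, `x_field`, `y_field`.
#' @method glance emm_correlation
#' @export
glance.emm_correlation <- function(x, ...) {
  tibble(
    n = x$n, r = x$r, r.squared = x$r_squared,
    statistic = x$statistic, p.value = x$p_value,
    slope = x$slope, intercept = x$intercept,
    x_field = x$x_field, y_field = x$y_field
  )
}

#' Tidy / glance methods for FVC comparisons
#'
#' `tidy()` returns the match table; `glance()` the background summary.
#'
#' @param x An `fvc_result` object.
#' @param ... Unused.
#' @method tidy fvc_result
#' @export
tidy.fvc_result <- function(x, ...) x$matches

#' @rdname tidy.fvc_result
#' @method glance fvc_result
#' @export
glance.fvc_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble(id_a = x$meta$id_a, id_b = x$meta$id_b, L = x$meta$L),
    x$background$summary,
    tibble(n_undefined = x$meta$n_undefined)
  )
}
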