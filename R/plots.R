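#' Plot a thermodynamic profile
#'
#' Per-residue descriptor traces, facetted by descriptor, coloured by
#' state.
#'
#' @param object A `thermo_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot thermo_profile
#' @export
autoplot.thermo_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    cols = dplyr::all_of(descriptor_cols()),
    names_to = c("descriptor", "state"),
    names_pattern = "(dG|dH_ap|dH_pol|TdS_conf)_(native|denatured)"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pos, y = .data$value,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~descriptor, scales = "free_y") +
    ggplot2::labs(x = "Residue", y = "kcal/mol",
                  title = unique(object$id)[1])
}

#' Plot an EMM correlation
#'
#' Scatter of chip binding versus the computed similarity with the
#' least-squares line and the fit statistics in the subtitle.
#'
#' @param object An `emm_correlation` from [correlate_pairs()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot emm_correlation
#' @export
autoplot.emm_correlation <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::labs(
      x = object$x_field, y = object$y_field,
      subtitle = sprintf("n = %d, r^2 = %.3f, p = %.2g",
                         object$n, object$r_squared, object$p_value)
    )
}

#' Plot an epitope register against its FVC background
#'
#' Box-and-whisker of the all-pairs cosine background with the published
#' epitope register's score overlaid in red and the background mean as a
#' horizontal line.
#'
#' @param object An `epitope_test` from [epitope_background_test()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot epitope_test
#' @export
autoplot.epitope_test <- function(object, ...) {
  bg <- attr(object, "background")
  df <- tibble(pair = paste(object$id_a, object$id_b, sep = " / "),
               cosine = bg$scores)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair, y = .data$cosine)) +
    ggplot2::geom_boxplot(fill = "lightsteelblue", outlier.alpha = 0.2) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.5,
                          linewidth = 0.3) +
    ggplot2::annotate("point", x = 1, y = object$epitope_cosine,
                      colour = "red", size = 3) +
    ggplot2::labs(x = NULL, y = "FVC cosine similarity",
                  subtitle = sprintf("epitope register (%d, %d), L = %d",
                                     object$start_a, object$start_b,
                                     object$L))
}
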