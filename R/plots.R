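#' Plot the standardized variance decomposition of a fit
#'
#' Stacked bars of the A/C/E variance fractions at each visit.
#'
#' @param object A `cholesky_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cholesky_fit
#' @export
autoplot.cholesky_fit <- function(object, ...) {
  std <- standardized_components(object)
  ggplot2::ggplot(std, ggplot2::aes(x = factor(.data$visit),
                                    y = .data$fraction,
                                    fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = "Visit", y = "Fraction of phenotypic variance",
                  fill = "Component",
                  title = "Standardized variance components") +
    ggplot2::theme_minimal()
}

#' Plot the likelihood-ratio ladder
#'
#' Chi-square p-values for each rung of the model ladder and path tests,
#' with the selection threshold drawn as a reference line.
#'
#' @param object A `chol_ladder`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot chol_ladder
#' @export
autoplot.chol_ladder <- function(object, ...) {
  d <- tidy(object)
  d <- d[!is.na(d$p_value), , drop = FALSE]
  d$comparison <- factor(d$comparison, levels = rev(d$comparison))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$p_value, y = .data$comparison,
                                  colour = .data$stage)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_vline(xintercept = object$alpha, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "LRT p-value (log scale)", y = NULL, colour = NULL,
                  title = "Model ladder likelihood-ratio tests") +
    ggplot2::theme_minimal()
}

#' Plot twin correlations by stratum
#'
#' Bar chart of the double-entry twin correlations per zygosity, visit and
#' ethnicity — the visual analogue of the classic twin-correlation table
#' (MZ bars exceeding DZ bars indicate genetic influence).
#'
#' @param data A twin table.
#' @param ... Passed to [twin_correlations()].
#' @return A ggplot object.
#' @export
plot_twin_correlations <- function(data, ...) {
  d <- twin_correlations(data, ...)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$zygosity, y = .data$r,
                                  fill = factor(.data$visit))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~ethnicity) +
    ggplot2::scale_fill_brewer(palette = "Paired") +
    ggplot2::labs(x = "Zygosity", y = "Twin correlation (double entry)",
                  fill = "Visit") +
    ggplot2::theme_minimal()
}
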