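# ggplot2 displays for the main result types.

#' Plot cumulative exceedance curves with their uncertainty band
#'
#' @param object an `exceedance_curve` tibble from
#'   [cumulative_exceedance_curve()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.exceedance_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$tau_label <- ifelse(is.na(df$tau), "all",
                         sprintf("%dth quantile", round(df$tau * 100)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = .data$prop))
  if (all(is.finite(df$prop_lower))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$prop_lower, ymax = .data$prop_upper),
      fill = "steelblue", alpha = 0.25)
  }
  p +
    ggplot2::geom_step(colour = "steelblue4") +
    ggplot2::facet_wrap(~tau_label) +
    ggplot2::labs(
      x = "probability of fish biodiversity loss",
      y = "cumulative proportion of stream reaches",
      title = "Reaches exceeding a given loss probability"
    ) +
    ggplot2::theme_minimal()
}

#' Wedge plot: richness residuals vs alteration with fitted quantile lines
#'
#' @param observations fish observation tibble with `richness_residual`.
#' @param fits optional [fit_quantile_models()] table to overlay.
#' @param metric alteration column to plot (default `"ha"`).
#' @return a ggplot.
#' @export
plot_wedge <- function(observations, fits = NULL, metric = "ha") {
  p <- ggplot2::ggplot(observations,
                       ggplot2::aes(x = .data[[metric]],
                                    y = .data$richness_residual)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = sprintf("hydrologic alteration (%s)", metric),
                  y = "fish richness residual (species)") +
    ggplot2::theme_minimal()
  if (!is.null(fits)) {
    f <- fits[fits$metric == metric, ]
    if (nrow(f)) {
      p <- p + ggplot2::geom_abline(
        data = f,
        ggplot2::aes(intercept = .data$beta0, slope = .data$beta1,
                     colour = factor(.data$tau)))
      p <- p + ggplot2::labs(colour = "quantile")
    }
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
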