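#' Scatter plot of a longevity-abundance regression
#'
#' @param object a `range_ols` from [fit_longevity_ols()].
#' @param ... unused.
#' @return A ggplot: observed points, the fitted line and its confidence
#'   band, annotated with R² and the slope p-value.
#' @method autoplot range_ols
#' @export
autoplot.range_ols <- function(object, ...) {
  d <- augment(object)
  g <- glance(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, color = "steelblue") +
    ggplot2::labs(
      x = object$predictor, y = paste0(object$response, " (my)"),
      title = object$label,
      subtitle = sprintf("R² = %.3f, p = %.3g, n = %d",
                         g$r_squared, g$p_value, g$n)
    ) +
    ggplot2::theme_minimal()
}

#' Residual-versus-fitted plot
#'
#' @param model a `range_ols`.
#' @return A ggplot of residuals against fitted values with a loess guide.
#' @export
plot_residuals <- function(model) {
  d <- augment(model)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$.fitted, y = .data$.resid)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         color = "firebrick") +
    ggplot2::labs(x = "fitted longevity (my)", y = "residual (my)",
                  title = model$label) +
    ggplot2::theme_minimal()
}

#' Violin/box plot of longevity by group
#'
#' The standard visual check that species longevities do (not) differ
#' among taxonomic orders or biogeographic categories.
#'
#' @param data per-species tibble (typically included species from
#'   [species_table()]).
#' @param group unquoted grouping column, e.g. `order_code`.
#' @return A ggplot.
#' @export
plot_longevity_groups <- function(data, group) {
  grp <- rlang::ensym(group)
  d <- data |>
    dplyr::filter(is.finite(.data$longevity), !is.na(!!grp))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(!!grp), y = .data$longevity)) +
    ggplot2::geom_violin(fill = "grey85", color = NA) +
    ggplot2::geom_boxplot(width = 0.15, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = rlang::as_string(grp), y = "longevity (my)") +
    ggplot2::theme_minimal()
}

#' Per-sample richness through time
#'
#' @param table an [occurrence_table()].
#' @return A ggplot of raw species richness against sample age (time runs
#'   left to right, oldest first).
#' @export
plot_richness <- function(table) {
  d <- sample_richness(table)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age, y = .data$richness)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "age (Ma)", y = "species per sample") +
    ggplot2::theme_minimal()
}
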