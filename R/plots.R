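#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a null-model test: observed value against the null interval
#'
#' @param object A `null_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot null_test
#' @export
autoplot.null_test <- function(object, ...) {
  d <- object$results
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      width = 0.2, colour = "grey40"
    ) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$null_mean), shape = 1, size = 2
    ) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$observed, colour = .data$verdict), size = 3
    ) +
    ggplot2::labs(
      y = d$metric[1],
      title = sprintf("%s under the %s null model", d$metric[1], d$model[1]),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot the random placement curve with observed richness
#'
#' Expected richness with a one-standard-deviation band against area
#' (log axis for display only), observed richness as points.
#'
#' @param object A `random_placement` result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot random_placement
#' @export
autoplot.random_placement <- function(object, ...) {
  d <- object$sites
  ggplot2::ggplot(d, ggplot2::aes(x = .data$area)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$expected - .data$sd,
                   ymax = .data$expected + .data$sd),
      fill = "grey80"
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected)) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$observed, colour = .data$within_1sd), size = 2
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "site area (ha, log scale)", y = "species richness",
      colour = "within 1 SD",
      title = sprintf(
        "random placement: %.0f%% of sites outside 1 SD",
        100 * object$fraction_outside
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a rarefaction/extrapolation richness curve
#'
#' @param curve A tibble from [richness_curve()], optionally with a `group`
#'   column to colour multiple curves.
#' @return A ggplot.
#' @export
plot_richness_curve <- function(curve) {
  aes_line <- if ("group" %in% names(curve)) {
    ggplot2::aes(x = .data$m, y = .data$richness,
                 colour = .data$group, linetype = .data$method)
  } else {
    ggplot2::aes(x = .data$m, y = .data$richness, linetype = .data$method)
  }
  ggplot2::ggplot(dplyr::filter(curve, .data$method != "observed"), aes_line) +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = dplyr::filter(curve, .data$method == "observed"),
      mapping = if ("group" %in% names(curve)) {
        ggplot2::aes(x = .data$m, y = .data$richness, colour = .data$group)
      } else {
        ggplot2::aes(x = .data$m, y = .data$richness)
      },
      inherit.aes = FALSE, size = 2
    ) +
    ggplot2::scale_linetype_manual(
      values = c(rarefaction = "solid", extrapolation = "dashed")
    ) +
    ggplot2::labs(
      x = "individuals sampled", y = "expected species richness",
      linetype = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot the treeNODF decomposition
#'
#' @param object A `tree_nodf_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tree_nodf_result
#' @export
autoplot.tree_nodf_result <- function(object, ...) {
  d <- tidy(object)
  d$component <- factor(d$component, levels = c("treeNODF", "S.Fraction", "topoNODF"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(y = "value (0-100)", x = NULL,
                  title = "functional nestedness decomposition") +
    ggplot2::theme_minimal()
}
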