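#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the fitted index-coefficient function
#'
#' Fitted g(u'alpha_hat) against the estimated scalar index, with the
#' per-unit fitted values as points and the spline curve evaluated on a
#' fine grid.
#'
#' @param object a `sisar_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot sisar_fit
#' @export
autoplot.sisar_fit <- function(object, ...) {
  pts <- tibble::tibble(t = object$index, g = object$g_hat)
  grid <- tibble::tibble(t = seq(min(pts$t), max(pts$t), length.out = 200))
  grid$g <- eval_g(grid$t, object$basis, object$delta)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$t, y = .data$g)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "index t = u'alpha", y = "fitted g(t)",
                  title = "Estimated spatial autocorrelation function") +
    ggplot2::theme_minimal()
}

#' Moran scatterplot
#'
#' Deviations against their spatial lags, quadrant-coloured, with the
#' least-squares line whose slope equals Moran's I for a row-standardized
#' weight matrix.
#'
#' @param y numeric vector.
#' @param W a [spatial_weights] object or matrix.
#' @return A ggplot object.
#' @export
plot_moran_scatter <- function(y, W) {
  sc <- moran_scatter(y, W)
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$deviation, y = .data$lag,
                                   colour = .data$quadrant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(ggplot2::aes(group = 1), method = "lm",
                         formula = y ~ x, se = FALSE, colour = "black",
                         linewidth = 0.4) +
    ggplot2::labs(x = "deviation from the mean", y = "spatial lag of deviation",
                  title = "Moran scatterplot") +
    ggplot2::theme_minimal()
}

#' Histograms and Q-Q panels of Monte Carlo draws
#'
#' @param object an `mc_result`.
#' @param parameters which parameters to show (default: all).
#' @param type `"histogram"` or `"qq"`.
#' @param ... unused.
#' @return A ggplot object faceted by parameter.
#' @method autoplot mc_result
#' @export
autoplot.mc_result <- function(object, parameters = colnames(object$draws),
                               type = c("histogram", "qq"), ...) {
  type <- match.arg(type)
  if (type == "histogram") {
    long <- purrr::map_dfr(parameters, function(p) {
      h <- estimate_distribution_summary(object, p)$histogram
      dplyr::mutate(h, parameter = p)
    })
    truths <- object$table[match(parameters, object$table$parameter), ]
    ggplot2::ggplot(long, ggplot2::aes(x = .data$mid, y = .data$count)) +
      ggplot2::geom_col(width = long$upper - long$lower, fill = "steelblue",
                        colour = "white") +
      ggplot2::geom_vline(data = truths,
                          ggplot2::aes(xintercept = .data$true_value),
                          colour = "firebrick", linetype = 2, na.rm = TRUE) +
      ggplot2::facet_wrap(~parameter, scales = "free") +
      ggplot2::labs(x = "estimate", y = "count") +
      ggplot2::theme_minimal()
  } else {
    long <- purrr::map_dfr(parameters, function(p) {
      q <- estimate_distribution_summary(object, p)$qq
      dplyr::mutate(q, parameter = p)
    })
    ggplot2::ggplot(long, ggplot2::aes(x = .data$theoretical, y = .data$sample)) +
      ggplot2::geom_abline(colour = "grey60") +
      ggplot2::geom_point(size = 0.7, alpha = 0.7) +
      ggplot2::facet_wrap(~parameter) +
      ggplot2::labs(x = "normal quantiles", y = "standardized estimates") +
      ggplot2::theme_minimal()
  }
}
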