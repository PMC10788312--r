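#' Plot a performance surface with its ridge line
#'
#' Filled contour of performance over the (ornament, compensation) plane,
#' with the best-compensation ridge line and, optionally, the evolved
#' state under a sexual-selection gradient `s` and the manipulation path
#' leading left from it.
#'
#' @param object A [performance_surface()].
#' @param xlim,ylim Plot ranges for ornament and compensation.
#' @param s Optional sexual-selection gradient; when supplied the evolved
#'   state and the ornament-reduction path are overlaid.
#' @param n Grid resolution per axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot performance_surface
#' @export
autoplot.performance_surface <- function(object, xlim = c(0, 10),
                                         ylim = c(0, 10), s = NULL,
                                         n = 101, ...) {
  grid <- tidyr::expand_grid(x1 = seq(xlim[1], xlim[2], length.out = n),
                             x2 = seq(ylim[1], ylim[2], length.out = n))
  grid$performance <- evaluate_performance(object, grid$x1, grid$x2)
  p <- ggplot2::ggplot(grid, ggplot2::aes(.data$x1, .data$x2)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$performance)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$performance),
                          colour = "white", alpha = 0.4) +
    ggplot2::labs(x = "ornament expression", y = "compensatory trait") +
    ggplot2::theme_minimal()
  if (object$gamma22 < 0) {
    ridge <- tibble(x1 = seq(xlim[1], xlim[2], length.out = n))
    ridge$x2 <- ridge_compensation(object, ridge$x1)
    p <- p + ggplot2::geom_line(data = ridge, linetype = "dotted",
                                colour = "white")
  }
  if (!is.null(s)) {
    st <- current_state(object, s)
    path <- manipulation_path(object, s,
                              seq(0, st$x1_star, length.out = 50))
    p <- p +
      ggplot2::geom_path(data = path, ggplot2::aes(.data$x1, .data$x2),
                         colour = "skyblue", linewidth = 1) +
      ggplot2::geom_point(data = st,
                          ggplot2::aes(.data$x1_star, .data$x2_star),
                          colour = "black", size = 2)
  }
  p
}

#' Plot a manipulation path or cost-curve table
#'
#' @param path A tibble from [manipulation_path()] or [cost_curve_table()].
#' @param y Which column to draw: `"performance"` or `"cost"`.
#' @return A ggplot object.
#' @export
plot_manipulation_path <- function(path, y = c("performance", "cost")) {
  y <- match.arg(y)
  ggplot2::ggplot(path, ggplot2::aes(.data$x1, .data[[y]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "ornament expression", y = y) +
    ggplot2::theme_minimal()
}

#' Plot a fitted stability model over the averaged data
#'
#' Points are the per-cell mean angles (coloured by individual); the line
#' is the posterior-mean quadratic on the scaled manipulation axis, with
#' a 95% credible band from the pooled draws.
#'
#' @param object A [fit_stability_lmm()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stability_fit
#' @export
autoplot.stability_fit <- function(object, ...) {
  d <- object$design
  df <- tibble(z = d$X[, "linear"], y = d$y, individual = d$groups)
  zs <- seq(d$z_range[1], d$z_range[2], length.out = 100)
  pooled <- do.call(rbind, object$chains)
  pred <- vapply(zs, function(z) {
    draws <- pooled[, "intercept"] + pooled[, "linear"] * z +
      pooled[, "quadratic"] * z^2
    c(mean(draws), stats::quantile(draws, c(0.025, 0.975)))
  }, numeric(3))
  band <- tibble(z = zs, fit = pred[1, ], lo = pred[2, ], hi = pred[3, ])
  ggplot2::ggplot(df, ggplot2::aes(.data$z, .data$y)) +
    ggplot2::geom_ribbon(data = band,
                         ggplot2::aes(x = .data$z, ymin = .data$lo,
                                      ymax = .data$hi),
                         inherit.aes = FALSE, alpha = 0.2) +
    ggplot2::geom_line(data = band,
                       ggplot2::aes(.data$z, .data$fit),
                       inherit.aes = FALSE) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$individual)) +
    ggplot2::labs(x = "scaled manipulation", y = "mean |tilt| (deg)",
                  colour = "individual") +
    ggplot2::theme_minimal()
}
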