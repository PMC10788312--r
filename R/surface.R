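#' Bivariate quadratic performance surface
#'
#' Constructs a performance surface in the standard quadratic
#' (Lande--Arnold) form used to approximate selection and performance
#' landscapes over two traits,
#' \deqn{W(x_1, x_2) = \tfrac12\gamma_{11}x_1^2 + \beta_1 x_1 +
#'   \tfrac12\gamma_{22}x_2^2 + \beta_2 x_2 + \gamma_{12}x_1x_2 + \alpha,}
#' where \eqn{x_1} is the expression of a (sexually selected) ornament and
#' \eqn{x_2} the expression of a compensatory trait. The curvatures
#' \eqn{\gamma_{11}, \gamma_{22}} and the interaction \eqn{\gamma_{12}}
#' control the geometry (elliptical peak, saddle, or a perfectly
#' compensating ridge); \eqn{\beta_1, \beta_2} are directional gradients.
#'
#' The regime of interest for compensatory-trait coevolution is
#' \eqn{\gamma_{11} < 0}, \eqn{\gamma_{22} < 0}, \eqn{\gamma_{12} > 0}:
#' both traits are costly on their own but the compensatory trait offsets
#' part of the ornament's cost. `in_compensation_regime()` tests exactly
#' this predicate.
#'
#' @param gamma11,gamma22 Quadratic curvatures along the ornament and
#'   compensation axes (unitless).
#' @param gamma12 Interaction curvature; positive values mean the traits
#'   compensate each other.
#' @param beta1,beta2 Linear selection gradients (default 0, the pure
#'   curvature case).
#' @param alpha Constant offset (default 0).
#' @return An object of class `performance_surface`.
#' @examples
#' surf <- performance_surface(-8, -8, 7)
#' evaluate_performance(surf, 1, 1)
#' classify_geometry(surf)
#' @export
performance_surface <- function(gamma11, gamma22, gamma12,
                                beta1 = 0, beta2 = 0, alpha = 0) {
  coefs <- list(gamma11 = gamma11, gamma22 = gamma22, gamma12 = gamma12,
                beta1 = beta1, beta2 = beta2, alpha = alpha)
  for (nm in names(coefs)) check_scalar(coefs[[nm]], nm)
  structure(coefs, class = "performance_surface")
}

#' @export
print.performance_surface <- function(x, ...) {
  cat("<performance_surface>\n")
  cat(sprintf("  0.5*(%g)x1^2 + (%g)x1 + 0.5*(%g)x2^2 + (%g)x2 + (%g)x1*x2 + (%g)\n",
              x$gamma11, x$beta1, x$gamma22, x$beta2, x$gamma12, x$alpha))
  cat(sprintf("  geometry: %s\n", classify_geometry(x)))
  invisible(x)
}

#' @rdname performance_surface
#' @param surface A `performance_surface`.
#' @export
in_compensation_regime <- function(surface) {
  stopifnot(inherits(surface, "performance_surface"))
  surface$gamma11 < 0 && surface$gamma22 < 0 && surface$gamma12 > 0
}

#' Evaluate a performance surface
#'
#' @param surface A [performance_surface()].
#' @param x1,x2 Ornament and compensation coordinates; vectorised and
#'   recycled to a common length.
#' @return Numeric vector of performance values.
#' @export
evaluate_performance <- function(surface, x1, x2) {
  stopifnot(inherits(surface, "performance_surface"))
  check_finite_vec(x1, "x1")
  check_finite_vec(x2, "x2")
  0.5 * surface$gamma11 * x1^2 + surface$beta1 * x1 +
    0.5 * surface$gamma22 * x2^2 + surface$beta2 * x2 +
    surface$gamma12 * x1 * x2 + surface$alpha
}

#' Classify the geometry of a performance surface
#'
#' For surfaces with both curvatures negative, the sign of
#' \eqn{\gamma_{12}^2 - \gamma_{11}\gamma_{22}} decides the shape:
#' negative gives a single elliptical peak, positive a saddle, and zero
#' (within tolerance) the degenerate ridge along which the ornament's cost
#' is perfectly compensated. Surfaces with a non-negative curvature are
#' reported `not_applicable`.
#'
#' @inheritParams evaluate_performance
#' @param tol Relative tolerance for the degenerate (ridge) case.
#' @return One of `"elliptical_peak"`, `"saddle"`,
#'   `"perfect_compensation_ridge"`, `"not_applicable"`.
#' @export
classify_geometry <- function(surface, tol = 1e-9) {
  stopifnot(inherits(surface, "performance_surface"))
  if (surface$gamma11 >= 0 || surface$gamma22 >= 0) return("not_applicable")
  disc <- surface$gamma12^2 - surface$gamma11 * surface$gamma22
  scale <- max(abs(surface$gamma12^2), abs(surface$gamma11 * surface$gamma22), 1)
  if (abs(disc) <= tol * scale) return("perfect_compensation_ridge")
  if (disc < 0) "elliptical_peak" else "saddle"
}

#' Best-compensation ridge line
#'
#' For a fixed ornament value, returns the compensation level that
#' maximises performance: \eqn{x_2^{ridge}(x_1) = -(\gamma_{12}x_1 +
#' \beta_2)/\gamma_{22}}. The locus of these points is the ridge line of
#' the surface; phenotypes on it are perfectly tuned to their ornament.
#'
#' @inheritParams evaluate_performance
#' @param x1 Ornament value(s).
#' @return Compensation value(s) maximising performance at each `x1`.
#' @export
ridge_compensation <- function(surface, x1) {
  stopifnot(inherits(surface, "performance_surface"))
  check_finite_vec(x1, "x1")
  if (surface$gamma22 >= 0) {
    abort("No interior maximum over compensation: gamma22 must be negative.",
          class = "ornacost_no_interior_maximum")
  }
  -(surface$gamma12 * x1 + surface$beta2) / surface$gamma22
}

#' Conditional cost curve at fixed compensation
#'
#' Experimentally manipulating the ornament moves \eqn{x_1} while the
#' compensatory trait stays at its current value \eqn{k}. Substituting
#' \eqn{x_2 = k} into the surface gives the one-dimensional quadratic
#' \deqn{W(x_1 \mid k) = \tfrac12\gamma_{11}x_1^2 + (\gamma_{12}k +
#'   \beta_1)x_1 + \tfrac12\gamma_{22}k^2 + \beta_2 k + \alpha,}
#' whose maximiser (for \eqn{\gamma_{11} < 0}) is
#' \eqn{x_1^{peak} = -(\gamma_{12}k + \beta_1)/\gamma_{11}}. Completing
#' the square, \eqn{W = \tfrac12\gamma_{11}(x_1 + (\gamma_{12}k +
#' \beta_1)/\gamma_{11})^2 + c}, so the maximiser is the negative of the
#' bracketed shift; with \eqn{k > 0}, \eqn{\gamma_{12} > 0} and
#' \eqn{\gamma_{11} < 0} it is strictly positive, which is what makes a
#' concave cost function possible for a purely sexually selected ornament.
#'
#' @inheritParams evaluate_performance
#' @param k Fixed compensation level.
#' @return An object of class `cost_curve` with fields `a`, `b`, `c`
#'   (quadratic, linear, constant coefficients), `k` and `peak_x1`.
#' @export
conditional_cost_curve <- function(surface, k) {
  stopifnot(inherits(surface, "performance_surface"))
  check_scalar(k, "k")
  if (surface$gamma11 == 0) {
    abort("Degenerate cost curve: gamma11 must be nonzero.",
          class = "ornacost_degenerate_curve")
  }
  b <- surface$gamma12 * k + surface$beta1
  structure(
    list(a = 0.5 * surface$gamma11,
         b = b,
         c = 0.5 * surface$gamma22 * k^2 + surface$beta2 * k + surface$alpha,
         k = k,
         peak_x1 = -b / surface$gamma11),
    class = "cost_curve")
}

#' @export
print.cost_curve <- function(x, ...) {
  cat("<cost_curve>\n")
  cat(sprintf("  W(x1 | k = %g) = (%g)x1^2 + (%g)x1 + (%g); peak at x1 = %g\n",
              x$k, x$a, x$b, x$c, x$peak_x1))
  invisible(x)
}

#' Evaluate a conditional cost curve
#'
#' @param curve A [conditional_cost_curve()].
#' @param x1 Ornament value(s).
#' @return Performance values along the curve.
#' @export
evaluate_cost_curve <- function(curve, x1) {
  stopifnot(inherits(curve, "cost_curve"))
  check_finite_vec(x1, "x1")
  curve$a * x1^2 + curve$b * x1 + curve$c
}

#' Classify the shape of a manipulation cost function
#'
#' Relative to the current ornament value, the conditional curve implies
#' one of: a *concave* cost function (reduction first improves, then
#' worsens performance: the peak lies strictly inside \eqn{(0,
#' x_1^{current})}), an *incremental* cost function (performance rises all
#' the way to zero ornament: peak at or below 0), a *flat* curve
#' (negligible coefficients), or a *decreasing* pattern (peak at or beyond
#' the current value, so any reduction lowers performance — the signature
#' of a trait held up by viability selection rather than compensation).
#'
#' @inheritParams evaluate_cost_curve
#' @param x1_current Current (pre-manipulation) ornament value, > 0.
#' @param tol Absolute tolerance below which coefficients count as zero.
#' @return One of `"concave"`, `"incremental"`, `"flat"`, `"decreasing"`.
#' @export
classify_cost_shape <- function(curve, x1_current, tol = 1e-9) {
  stopifnot(inherits(curve, "cost_curve"))
  check_scalar(x1_current, "x1_current")
  if (x1_current <= 0) {
    abort("`x1_current` must be positive.", class = "ornacost_invalid_input")
  }
  if (abs(curve$a) < tol && abs(curve$b) < tol) return("flat")
  if (curve$peak_x1 <= 0) return("incremental")
  if (curve$peak_x1 < x1_current) return("concave")
  "decreasing"
}

#' Tabulate a cost curve for export
#'
#' Evaluates the conditional curve on a grid and reports the cost as
#' best achievable performance minus performance at each point, so cost is
#' zero at the curve's peak and positive elsewhere.
#'
#' @inheritParams evaluate_cost_curve
#' @param x1 Grid of ornament values.
#' @return A tibble with columns `x1`, `performance`, `cost`.
#' @export
cost_curve_table <- function(curve, x1) {
  perf <- evaluate_cost_curve(curve, x1)
  best <- if (curve$a < 0) evaluate_cost_curve(curve, curve$peak_x1) else max(perf)
  tibble(x1 = x1, performance = perf, cost = best - perf)
}

#' Read or write a performance surface as a flat config file
#'
#' Surfaces are serialised as flat key--value entries
#' (`gamma11` ... `alpha`) in YAML or JSON, chosen by file extension.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_surface()` returns a `performance_surface`;
#'   `write_surface()` returns `path` invisibly.
#' @export
read_surface <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("gamma11", "gamma22", "gamma12")
  if (!all(need %in% names(vals))) {
    abort("Surface config must contain gamma11, gamma22 and gamma12.",
          class = "ornacost_invalid_input")
  }
  performance_surface(vals$gamma11, vals$gamma22, vals$gamma12,
                      vals$beta1 %||% 0, vals$beta2 %||% 0, vals$alpha %||% 0)
}

#' @rdname read_surface
#' @param surface A `performance_surface`.
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "performance_surface"))
  vals <- unclass(surface)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}
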