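#' Evolved phenotype under sexual plus viability selection
#'
#' Adds a linear sexual-selection surface \eqn{s\,x_1} (mating advantage
#' increasing with ornament expression) to the performance surface and
#' returns the phenotype maximising the sum. For an elliptical surface
#' this is the solution of the stationarity system
#' \deqn{\gamma_{11}x_1 + \gamma_{12}x_2 + \beta_1 + s = 0, \qquad
#'       \gamma_{12}x_1 + \gamma_{22}x_2 + \beta_2 = 0,}
#' so the evolved compensation always sits on the ridge line for the
#' evolved ornament, while sexual selection drags the ornament beyond the
#' performance peak. Saddle or degenerate surfaces make total fitness
#' unbounded and are refused.
#'
#' @inheritParams evaluate_performance
#' @param s Linear sexual-selection gradient on the ornament (\eqn{s \ge 0}).
#' @return A tibble with one row: `x1_star`, `x2_star`, `performance`.
#' @examples
#' surf <- performance_surface(-8, -8, 7)
#' current_state(surf, s = 10)   # (16/3, 14/3)
#' @export
current_state <- function(surface, s) {
  stopifnot(inherits(surface, "performance_surface"))
  check_scalar(s, "s")
  if (s < 0) abort("`s` must be non-negative.", class = "ornacost_invalid_input")
  if (classify_geometry(surface) != "elliptical_peak") {
    abort("Total fitness is unbounded: surface must have an elliptical peak.",
          class = "ornacost_unbounded_fitness")
  }
  A <- matrix(c(surface$gamma11, surface$gamma12,
                surface$gamma12, surface$gamma22), 2, 2)
  rhs <- -c(surface$beta1 + s, surface$beta2)
  sol <- solve(A, rhs)
  tibble(x1_star = sol[1], x2_star = sol[2],
         performance = evaluate_performance(surface, sol[1], sol[2]))
}

#' Performance along an ornament-reduction experiment
#'
#' Starting from the evolved state, reduces the ornament by each `delta`
#' while the compensatory trait stays frozen at its evolved value — the
#' trajectory a shortening experiment traces across the surface. Cost is
#' reported as the best performance attained along the path minus the
#' performance at each point, so the path's peak has zero cost.
#'
#' @inheritParams current_state
#' @param deltas Non-negative ornament reductions (same units as `x1`).
#' @return A tibble with columns `delta`, `x1`, `x2`, `performance`,
#'   `cost`, ordered as given. Empty `deltas` give an empty table.
#' @export
manipulation_path <- function(surface, s, deltas) {
  st <- current_state(surface, s)
  if (length(deltas) == 0L) {
    return(tibble(delta = double(), x1 = double(), x2 = double(),
                  performance = double(), cost = double()))
  }
  check_finite_vec(deltas, "deltas")
  if (any(deltas < 0)) {
    abort("`deltas` are reductions and must be >= 0.",
          class = "ornacost_invalid_input")
  }
  x1 <- st$x1_star - deltas
  perf <- evaluate_performance(surface, x1, rep(st$x2_star, length(x1)))
  curve <- conditional_cost_curve(surface, st$x2_star)
  best <- evaluate_cost_curve(curve, curve$peak_x1)
  tibble(delta = deltas, x1 = x1, x2 = st$x2_star,
         performance = perf, cost = best - perf)
}

#' Candidate morph grid for the balancing-toy game
#'
#' @param elongation_mm Tail elongations beyond the ancestral state (mm).
#' @param wings Compensatory-wing states to cross with the elongations.
#' @return A tibble of strategies with columns `tail_elongation_mm`, `wings`.
#' @export
toy_strategies <- function(elongation_mm = seq(0, 110, by = 10),
                           wings = c(FALSE, TRUE)) {
  check_finite_vec(elongation_mm, "elongation_mm")
  if (any(elongation_mm < 0)) {
    abort("Elongations must be >= 0.", class = "ornacost_invalid_input")
  }
  tidyr::expand_grid(tail_elongation_mm = elongation_mm, wings = wings)
}

#' Solve the survive-then-reproduce toy game
#'
#' The game has two sequential filters: a morph *survives* only if its
#' tilt away from horizontal is below the cutoff (viability selection via
#' balance), and among survivors only the longest-tailed morphs
#' *reproduce* (sexual selection). The evolutionarily stable set is
#' therefore the survivors of maximal tail elongation; ties return the
#' whole tie set. With no survivors the population is extinct: an empty
#' tibble is returned with a warning.
#'
#' @param strategies A tibble as from [toy_strategies()].
#' @param tilt_model Function `(tail_elongation_mm, wings) -> degrees`
#'   giving the deterministic tilt of each morph; defaults are built with
#'   [tilt_angle()] and calibrated parameters, see [run_pipeline()].
#' @param cutoff_deg Survival threshold on |tilt| (degrees, default 30).
#' @return Tibble of ESS strategies with their tilt angles.
#' @export
solve_toy_game <- function(strategies, tilt_model, cutoff_deg = 30) {
  stopifnot(is.data.frame(strategies), nrow(strategies) > 0L)
  check_scalar(cutoff_deg, "cutoff_deg")
  tilt <- purrr::map2_dbl(strategies$tail_elongation_mm, strategies$wings,
                          function(e, w) tilt_model(e, w))
  out <- strategies
  out$tilt_deg <- abs(tilt)
  survivors <- dplyr::filter(out, .data$tilt_deg < cutoff_deg)
  if (nrow(survivors) == 0L) {
    warn("No strategy survives the balance cutoff: population extinct.")
    return(survivors)
  }
  dplyr::filter(survivors,
                .data$tail_elongation_mm == max(.data$tail_elongation_mm))
}
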