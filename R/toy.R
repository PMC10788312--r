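#' Physical parameters of the balancing-toy simulator
#'
#' The simulator stands in for a physical balancing toy (a "chuonchuon"):
#' a plastic-straw tail (0.4 g per 160 mm, cut from the far end by the
#' manipulation) loads one side of the pivot, and a pair of clay wings
#' (0.8 g each) the other. Tilt is modelled as linear in the net moment
#' (small-angle approximation): the tail moment is the mass of the
#' remaining straw times a fixed lever arm, the wing moment is the two
#' wing masses times their arm, and
#' `angle = |baseline + angle_scale * (tail moment - wing moment) +
#' individual effect + noise|`, clipped at 90 degrees. The lever arms and
#' `angle_scale` are free calibration constants, not measurements of the
#' toy; see [calibrate_generator()].
#'
#' @param straw_mass_g,straw_length_mm Full straw mass (g) and length (mm);
#'   mass removed by shortening is proportional to length removed.
#' @param full_elongation_mm Tail added at manipulation 0 (mm). 110 by
#'   construction: a -80 mm manipulation must leave 30 mm of elongation.
#' @param wing_mass_g Mass of each of the two wings (g).
#' @param tail_arm_mm,wing_arm_mm Lever arms (mm) of the tail midpoint and
#'   the wing masses about the pivot.
#' @param angle_scale Degrees of tilt per unit net moment (deg per g mm).
#' @param baseline_deg Tilt of the bare ancestral toy (deg).
#' @param sigma_individual_deg SD of the per-toy baseline offset (deg).
#' @param sigma_meas_deg SD of per-photo measurement noise (deg).
#' @param cutoff_deg Balance cutoff used by the survival filter (deg).
#' @return An object of class `toy_params`.
#' @export
toy_params <- function(straw_mass_g = 0.4,
                       straw_length_mm = 160,
                       full_elongation_mm = 110,
                       wing_mass_g = 0.8,
                       tail_arm_mm = 40,
                       wing_arm_mm = 5.840886,
                       angle_scale = 10.576667,
                       baseline_deg = 4.87,
                       sigma_individual_deg = 0.45,
                       sigma_meas_deg = 2,
                       cutoff_deg = 30) {
  p <- list(straw_mass_g = straw_mass_g, straw_length_mm = straw_length_mm,
            full_elongation_mm = full_elongation_mm, wing_mass_g = wing_mass_g,
            tail_arm_mm = tail_arm_mm, wing_arm_mm = wing_arm_mm,
            angle_scale = angle_scale, baseline_deg = baseline_deg,
            sigma_individual_deg = sigma_individual_deg,
            sigma_meas_deg = sigma_meas_deg, cutoff_deg = cutoff_deg)
  for (nm in names(p)) check_scalar(p[[nm]], nm)
  nonneg <- c("straw_mass_g", "straw_length_mm", "full_elongation_mm",
              "wing_mass_g", "sigma_individual_deg", "sigma_meas_deg")
  for (nm in nonneg) {
    if (p[[nm]] < 0) abort(sprintf("`%s` must be >= 0.", nm),
                           class = "ornacost_invalid_input")
  }
  if (p$cutoff_deg <= 0) abort("`cutoff_deg` must be > 0.",
                               class = "ornacost_invalid_input")
  structure(p, class = "toy_params")
}

#' @export
print.toy_params <- function(x, ...) {
  cat("<toy_params>\n")
  cat(sprintf("  straw %.3g g / %.4g mm, wings 2 x %.3g g\n",
              x$straw_mass_g, x$straw_length_mm, x$wing_mass_g))
  cat(sprintf("  arms: tail %.4g mm, wing %.4g mm; scale %.4g deg/(g mm); baseline %.4g deg\n",
              x$tail_arm_mm, x$wing_arm_mm, x$angle_scale, x$baseline_deg))
  cat(sprintf("  noise: individual %.3g deg, photo %.3g deg; cutoff %.3g deg\n",
              x$sigma_individual_deg, x$sigma_meas_deg, x$cutoff_deg))
  invisible(x)
}

# net moment (g mm) of a toy with `added_mm` of tail beyond ancestral
net_moment <- function(params, added_mm, wings) {
  tail_mass <- params$straw_mass_g * added_mm / params$straw_length_mm
  tail_mass * params$tail_arm_mm -
    ifelse(wings, 2 * params$wing_mass_g * params$wing_arm_mm, 0)
}

#' Tilt angle of a (possibly manipulated) toy morph
#'
#' Deterministic unless `individual_effect` or `noise_deg` are supplied;
#' those enter additively in degrees before the absolute value, matching
#' the random-intercept structure assumed by the downstream mixed model.
#' A manipulation cutting more than the available elongation is clamped to
#' the bare ancestral tail with a warning.
#'
#' @param params A [toy_params()].
#' @param tail_elongation_mm Tail added beyond the ancestral state (mm,
#'   vectorised).
#' @param wings Logical: compensatory wings present (vectorised).
#' @param manipulation_mm Experimental shortening, <= 0 (mm).
#' @param individual_effect Per-toy baseline offset (deg).
#' @param noise_deg Per-photo measurement noise (deg).
#' @return Absolute tilt from horizontal in degrees, clipped at 90.
#' @examples
#' p <- toy_params()
#' tilt_angle(p, 0, wings = FALSE)              # ancestral, ~4.87
#' tilt_angle(p, 110, wings = TRUE)             # full ESS morph, ~22.4
#' tilt_angle(p, 110, wings = TRUE, manipulation_mm = -80)
#' @export
tilt_angle <- function(params, tail_elongation_mm, wings,
                       manipulation_mm = 0, individual_effect = 0,
                       noise_deg = 0) {
  stopifnot(inherits(params, "toy_params"))
  check_finite_vec(tail_elongation_mm, "tail_elongation_mm")
  if (any(manipulation_mm > 0)) {
    abort("`manipulation_mm` is a shortening and must be <= 0.",
          class = "ornacost_invalid_input")
  }
  added <- tail_elongation_mm + manipulation_mm
  if (any(added < 0)) {
    warn("Manipulation exceeds available elongation; clamped to bare tail.")
    added <- pmax(added, 0)
  }
  raw <- params$baseline_deg +
    params$angle_scale * net_moment(params, added, wings) +
    individual_effect + noise_deg
  pmin(abs(raw), 90)
}

#' Calibrate the simulator to three anchor morphs
#'
#' Solves for `baseline_deg`, `angle_scale` and `wing_arm_mm` so that the
#' noise-free tilt of three reference morphs matches supplied anchor
#' means: the ancestral toy (no elongation, no wings), the fully elongated
#' winged morph, and a wingless morph with 30 mm of elongation. In the
#' parameterisation (baseline, angle_scale, angle_scale x wing moment) the
#' three conditions are linear, so the least-squares fit over them is
#' solved exactly; the residuals and per-anchor relative errors are kept
#' on the result for inspection.
#'
#' @param anchor_means Named numeric: `ancestral`, `ess_full`,
#'   `wingless_30mm`, in degrees; all positive.
#' @param params Baseline [toy_params()] supplying masses, lengths and the
#'   tail arm, which are held fixed.
#' @param tol Maximum admissible relative error at any anchor.
#' @return A `toy_params` with calibrated `baseline_deg`, `angle_scale`,
#'   `wing_arm_mm` and an attribute `calibration` (tibble of anchors,
#'   fitted means and relative errors).
#' @export
calibrate_generator <- function(anchor_means = c(ancestral = 4.87,
                                                 ess_full = 22.37,
                                                 wingless_30mm = 36.60),
                                params = toy_params(),
                                tol = 0.05) {
  need <- c("ancestral", "ess_full", "wingless_30mm")
  if (!all(need %in% names(anchor_means))) {
    abort("`anchor_means` must name ancestral, ess_full and wingless_30mm.",
          class = "ornacost_invalid_input")
  }
  a <- anchor_means[need]
  check_finite_vec(unname(a), "anchor_means")
  if (any(a <= 0)) abort("Anchor means must be positive.",
                         class = "ornacost_invalid_input")

  dens <- params$straw_mass_g / params$straw_length_mm
  tmom <- function(added) dens * added * params$tail_arm_mm
  # columns: baseline, angle_scale (x tail moment), angle_scale*wing_moment
  X <- rbind(c(1, tmom(0),                         0),
             c(1, tmom(params$full_elongation_mm), -1),
             c(1, tmom(30),                        0))
  fit <- stats::lm.fit(X, as.numeric(a[c("ancestral", "ess_full",
                                         "wingless_30mm")]))
  theta <- fit$coefficients
  if (!all(is.finite(theta)) || abs(theta[2]) < 1e-12) {
    abort(paste0("Calibration degenerate: anchors imply angle_scale ~ 0 ",
                 "(residuals: ", paste(signif(fit$residuals, 3), collapse = ", "),
                 ")."),
          class = "ornacost_calibration_failure")
  }
  out <- params
  out$baseline_deg <- unname(theta[1])
  out$angle_scale <- unname(theta[2])
  out$wing_arm_mm <- unname(theta[3] / (theta[2] * 2 * params$wing_mass_g))

  fitted <- c(
    ancestral = tilt_angle(out, 0, FALSE),
    ess_full = tilt_angle(out, out$full_elongation_mm, TRUE),
    wingless_30mm = tilt_angle(out, 30, FALSE))
  rel_err <- abs(fitted - a) / a
  if (any(rel_err > tol)) {
    abort(paste0("Calibration infeasible: relative errors ",
                 paste(signif(rel_err, 3), collapse = ", "),
                 " exceed tolerance ", tol, "."),
          class = "ornacost_calibration_failure")
  }
  attr(out, "calibration") <- tibble(
    anchor = need, target_deg = as.numeric(a),
    fitted_deg = as.numeric(fitted), rel_error = as.numeric(rel_err))
  out
}

#' Generate a synthetic manipulation-experiment table
#'
#' Emulates the shortening experiment on the evolved morph (full
#' elongation, wings on): each toy gets a Gaussian individual baseline
#' offset, each photograph a Gaussian measurement error, and every
#' (individual, treatment) cell is photographed `replicates` times. The
#' default design is 4 individuals x 5 shortening treatments
#' (0, -20, -40, -60, -80 mm) x 2 replicates = 40 records. The same seed
#' always reproduces the identical table.
#'
#' @param params A [toy_params()], typically from [calibrate_generator()].
#' @param n_individuals Number of toys.
#' @param treatments Shortening treatments in mm (all <= 0).
#' @param replicates Photographs per (individual, treatment) cell.
#' @param seed Integer seed; required, so tables are reproducible.
#' @return A tibble with columns `individual_id` (factor),
#'   `treatment_mm`, `replicate`, `angle_deg`.
#' @export
generate_experiment <- function(params,
                                n_individuals = 4,
                                treatments = c(0, -20, -40, -60, -80),
                                replicates = 2,
                                seed) {
  stopifnot(inherits(params, "toy_params"))
  if (missing(seed)) abort("`seed` is required for reproducibility.",
                           class = "ornacost_invalid_input")
  check_scalar(seed, "seed")
  if (n_individuals < 1 || replicates < 1 || length(treatments) == 0L) {
    abort("Design must have >= 1 individual, treatment and replicate.",
          class = "ornacost_invalid_input")
  }
  if (any(treatments > 0)) {
    abort("Treatments are shortenings and must be <= 0.",
          class = "ornacost_invalid_input")
  }
  set.seed(as.integer(seed))
  ids <- sprintf("toy%02d", seq_len(n_individuals))
  ind_effect <- stats::rnorm(n_individuals, 0, params$sigma_individual_deg)
  design <- tidyr::expand_grid(individual_id = ids,
                               treatment_mm = treatments,
                               replicate = seq_len(replicates))
  noise <- stats::rnorm(nrow(design), 0, params$sigma_meas_deg)
  eff <- ind_effect[match(design$individual_id, ids)]
  design$angle_deg <- tilt_angle(params,
                                 rep(params$full_elongation_mm, nrow(design)),
                                 wings = TRUE,
                                 manipulation_mm = design$treatment_mm,
                                 individual_effect = eff,
                                 noise_deg = noise)
  design$individual_id <- factor(design$individual_id, levels = ids)
  design
}
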