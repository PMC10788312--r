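#' Average replicate photographs per cell
#'
#' Collapses an experiment table to one representative stability estimate
#' per (individual, treatment) cell by arithmetic mean of the replicate
#' angles. An incomplete crossing of individuals and treatments is an
#' error — the design is expected to be complete, and silent imputation
#' would bias the downstream fit.
#'
#' @param table An experiment table as from [generate_experiment()] or
#'   [read_experiment_csv()].
#' @return A tibble with columns `individual_id`, `treatment_mm`,
#'   `mean_angle_deg`, one row per cell.
#' @export
average_replicates <- function(table) {
  check_experiment_table(table)
  out <- table |>
    dplyr::group_by(.data$individual_id, .data$treatment_mm) |>
    dplyr::summarise(mean_angle_deg = mean(.data$angle_deg), .groups = "drop")
  n_cells <- length(unique(table$individual_id)) *
    length(unique(table$treatment_mm))
  if (nrow(out) != n_cells) {
    abort(sprintf("Missing cells: expected %d (individual, treatment) cells, found %d.",
                  n_cells, nrow(out)),
          class = "ornacost_missing_data")
  }
  out
}

#' ANOVA-based repeatability of replicate measurements
#'
#' Intraclass correlation from a one-way ANOVA over groups, following the
#' classical variance-component estimator: with among-group and
#' within-group mean squares \eqn{MS_A} and \eqn{MS_W} and effective group
#' size \eqn{n_0 = (N - \sum n_i^2/N)/(a-1)},
#' \deqn{s^2_A = (MS_A - MS_W)/n_0, \qquad r = s^2_A / (s^2_A + MS_W).}
#' For balanced groups of size \eqn{n_0} this reduces to
#' \eqn{r = (F-1)/(F-1+n_0)}. Groups default to the (individual,
#' treatment) cells, so `r` measures photo-to-photo repeatability within a
#' cell; grouping by individual alone is available but conflates
#' treatment effects with among-individual variance.
#'
#' @inheritParams average_replicates
#' @param group One of `"cell"` (individual x treatment, default) or
#'   `"individual"`.
#' @return A one-row tibble: `r`, `F`, `df_between`, `df_within`, `n0`.
#' @export
repeatability <- function(table, group = c("cell", "individual")) {
  check_experiment_table(table)
  group <- match.arg(group)
  g <- if (group == "cell") {
    interaction(table$individual_id, table$treatment_mm, drop = TRUE)
  } else {
    factor(table$individual_id)
  }
  y <- table$angle_deg
  a <- nlevels(g)
  N <- length(y)
  n_i <- as.numeric(table(g))
  if (a < 2) abort("Repeatability needs >= 2 groups.",
                   class = "ornacost_invalid_input")
  if (all(n_i == 1)) {
    abort("Repeatability undefined: every group has a single measurement.",
          class = "ornacost_undefined_repeatability")
  }
  gmeans <- tapply(y, g, mean)
  ss_between <- sum(n_i * (gmeans - mean(y))^2)
  ss_within <- sum((y - gmeans[g])^2)
  ms_a <- ss_between / (a - 1)
  ms_w <- ss_within / (N - a)
  n0 <- (N - sum(n_i^2) / N) / (a - 1)
  if (ms_w == 0) {
    return(tibble(r = 1, F = Inf, df_between = a - 1, df_within = N - a,
                  n0 = n0))
  }
  s2_a <- (ms_a - ms_w) / n0
  tibble(r = s2_a / (s2_a + ms_w), F = ms_a / ms_w,
         df_between = a - 1, df_within = N - a, n0 = n0)
}

#' Build the quadratic design for the stability model
#'
#' Scales the manipulation predictor, squares it for the quadratic term,
#' and returns the pieces the sampler needs. The default `"zscore"`
#' scaling centres and scales by the mean and (n-1) standard deviation of
#' the *distinct* treatment values, so for the standard design
#' \{0, -20, -40, -60, -80\} mm the scaled levels are
#' \{±1.2649, ±0.6325, 0\}; `"center"` only subtracts the mean of the
#' distinct levels, `"raw"` leaves millimetres untouched.
#'
#' @param table An averaged table from [average_replicates()].
#' @param scaling One of `"zscore"`, `"center"`, `"raw"`.
#' @return A list with `y` (response vector), `X` (matrix with columns
#'   `intercept`, `linear`, `quadratic`), `groups` (individual factor),
#'   `center`, `scale`, and `z_range` (range of the scaled predictor).
#' @export
build_design <- function(table, scaling = c("zscore", "center", "raw")) {
  scaling <- match.arg(scaling)
  stopifnot(is.data.frame(table))
  need <- c("individual_id", "treatment_mm", "mean_angle_deg")
  if (!all(need %in% names(table))) {
    abort("`table` must be an averaged table (individual_id, treatment_mm, mean_angle_deg).",
          class = "ornacost_invalid_input")
  }
  lev <- sort(unique(table$treatment_mm))
  if (length(lev) < 3) {
    abort("Quadratic term unidentifiable: need >= 3 distinct treatments.",
          class = "ornacost_rank_deficient")
  }
  center <- switch(scaling, raw = 0, mean(lev))
  scale <- switch(scaling, zscore = stats::sd(lev), 1)
  z <- (table$treatment_mm - center) / scale
  X <- cbind(intercept = 1, linear = z, quadratic = z^2)
  if (qr(X)$rank < 3) {
    abort("Design matrix is rank deficient.", class = "ornacost_rank_deficient")
  }
  list(y = table$mean_angle_deg, X = X,
       groups = factor(table$individual_id),
       center = center, scale = scale,
       z_range = range((lev - center) / scale))
}

# shared validation of the long experiment-table contract
check_experiment_table <- function(table) {
  stopifnot(is.data.frame(table))
  need <- c("individual_id", "treatment_mm", "replicate", "angle_deg")
  if (!all(need %in% names(table))) {
    abort(sprintf("Experiment table must have columns %s.",
                  paste(need, collapse = ", ")),
          class = "ornacost_invalid_input")
  }
  if (nrow(table) == 0L) {
    abort("Experiment table is empty.", class = "ornacost_invalid_input")
  }
  if (any(!is.finite(table$angle_deg)) || any(table$angle_deg < 0)) {
    abort("Angles must be finite and >= 0.", class = "ornacost_invalid_input")
  }
  invisible(table)
}
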