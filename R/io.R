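#' Read or write an experiment table as CSV
#'
#' The CSV dialect is comma-separated UTF-8 with the header
#' `individual_id,treatment_mm,replicate,angle_deg`; treatments are
#' signed millimetres, angles degrees. Malformed rows and duplicate
#' (individual, treatment, replicate) keys are errors, reported with the
#' offending line.
#'
#' @param path File path.
#' @return `read_experiment_csv()` returns the experiment tibble;
#'   `write_experiment_csv()` returns `path` invisibly.
#' @export
read_experiment_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "ornacost_invalid_input")
  }
  tab <- readr::read_csv(
    path,
    col_types = readr::cols(individual_id = readr::col_character(),
                            treatment_mm = readr::col_double(),
                            replicate = readr::col_integer(),
                            angle_deg = readr::col_double()))
  need <- c("individual_id", "treatment_mm", "replicate", "angle_deg")
  if (!all(need %in% names(tab))) {
    abort(sprintf("Header must contain %s.", paste(need, collapse = ", ")),
          class = "ornacost_invalid_input")
  }
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    abort(sprintf("Malformed CSV at line %d: expected %s, got '%s'.",
                  probs$row[1], probs$expected[1], probs$actual[1]),
          class = "ornacost_invalid_input")
  }
  bad <- which(!stats::complete.cases(tab))
  if (length(bad) > 0) {
    abort(sprintf("Malformed CSV at line %d: missing value.", bad[1] + 1L),
          class = "ornacost_invalid_input")
  }
  key <- paste(tab$individual_id, tab$treatment_mm, tab$replicate)
  if (anyDuplicated(key)) {
    abort(sprintf("Duplicate (individual, treatment, replicate) record at line %d.",
                  anyDuplicated(key) + 1L),
          class = "ornacost_invalid_input")
  }
  tab$individual_id <- factor(tab$individual_id,
                              levels = unique(tab$individual_id))
  check_experiment_table(tab)
  tab
}

#' @rdname read_experiment_csv
#' @param table An experiment table.
#' @export
write_experiment_csv <- function(table, path) {
  check_experiment_table(table)
  out <- dplyr::mutate(table,
                       individual_id = as.character(.data$individual_id),
                       angle_deg = signif(.data$angle_deg, 8))
  readr::write_csv(out, path)
  invisible(path)
}

#' Assemble and validate a pipeline configuration
#'
#' One object drives the whole analysis: the performance surface and
#' sexual-selection gradient for the theory stage, the calibration
#' anchors and design for the synthetic experiment, the predictor
#' scaling, the MCMC settings, and a single master seed from which each
#' stage deterministically derives its own substream. All defaults
#' reproduce the standard study setup. Unknown fields are rejected.
#'
#' @param surface A [performance_surface()].
#' @param s Sexual-selection gradient.
#' @param anchors Calibration anchor means, see [calibrate_generator()].
#' @param n_individuals,treatments,replicates Experiment design.
#' @param strategy_grid Tail-elongation grid for the ESS game (mm).
#' @param wings_allowed Include winged morphs in the game.
#' @param cutoff_deg Balance cutoff for the game.
#' @param scaling Predictor scaling for [build_design()].
#' @param mcmc An [mcmc_config()] (its own seed is overridden by `seed`).
#' @param seed Master seed.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(surface = performance_surface(-8, -8, 7),
                            s = 10,
                            anchors = c(ancestral = 4.87, ess_full = 22.37,
                                        wingless_30mm = 36.60),
                            n_individuals = 4,
                            treatments = c(0, -20, -40, -60, -80),
                            replicates = 2,
                            strategy_grid = seq(0, 110, by = 10),
                            wings_allowed = TRUE,
                            cutoff_deg = 30,
                            scaling = "zscore",
                            mcmc = mcmc_config(),
                            seed = 1) {
  cfg <- list(surface = surface, s = s, anchors = anchors,
              n_individuals = n_individuals, treatments = treatments,
              replicates = replicates, strategy_grid = strategy_grid,
              wings_allowed = wings_allowed, cutoff_deg = cutoff_deg,
              scaling = scaling, mcmc = mcmc, seed = seed)
  stopifnot(inherits(surface, "performance_surface"),
            inherits(mcmc, "mcmc_config"))
  check_scalar(s, "s"); check_scalar(seed, "seed")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat keys mirror the arguments of [pipeline_config()]; surface
#' coefficients sit under a `surface:` block and MCMC overrides under
#' `mcmc:`. Unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("surface", "s", "anchors", "n_individuals", "treatments",
             "replicates", "strategy_grid", "wings_allowed", "cutoff_deg",
             "scaling", "mcmc", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    abort(sprintf("Unknown config keys: %s.", paste(extra, collapse = ", ")),
          class = "ornacost_invalid_input")
  }
  args <- raw
  if (!is.null(raw$surface)) {
    args$surface <- do.call(performance_surface, raw$surface)
  }
  if (!is.null(raw$anchors)) args$anchors <- unlist(raw$anchors)
  if (!is.null(raw$mcmc)) args$mcmc <- do.call(mcmc_config, raw$mcmc)
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Wires the stages end to end: calibrate the toy simulator to the anchor
#' means, solve the ESS game on the strategy grid, generate the synthetic
#' shortening experiment for the ESS morph (or load a user CSV instead),
#' average replicates, compute repeatability, fit the Bayesian
#' random-intercept quadratic model, and classify the implied cost
#' function. The theory stage (evolved state and manipulation-path peak
#' of the configured surface) is reported alongside. Stage seeds are
#' derived deterministically from the master seed, so the same config
#' yields an identical report.
#'
#' @param config A [pipeline_config()].
#' @param csv_path Optional path to a measured experiment CSV; when given
#'   the generator is skipped and the data are analysed as-is.
#' @return A list of class `pipeline_report` with elements `calibration`,
#'   `ess`, `current_state`, `path_peak_x1`, `repeatability`,
#'   `coefficients`, `converged`, `verdict`, `seed`, and the `fit` itself.
#' @export
run_pipeline <- function(config = pipeline_config(), csv_path = NULL) {
  stopifnot(inherits(config, "pipeline_config"))

  params <- calibrate_generator(config$anchors)
  params$cutoff_deg <- config$cutoff_deg

  strategies <- toy_strategies(config$strategy_grid,
                               wings = if (config$wings_allowed)
                                 c(FALSE, TRUE) else FALSE)
  tilt_model <- function(e, w) tilt_angle(params, e, w)
  ess <- solve_toy_game(strategies, tilt_model, config$cutoff_deg)

  st <- current_state(config$surface, config$s)
  curve <- conditional_cost_curve(config$surface, st$x2_star)

  table <- if (is.null(csv_path)) {
    generate_experiment(params, config$n_individuals, config$treatments,
                        config$replicates,
                        seed = derive_seed(config$seed, "generate"))
  } else {
    read_experiment_csv(csv_path)
  }
  averaged <- average_replicates(table)
  rep_tab <- repeatability(table)

  mc <- config$mcmc
  mc$seed <- derive_seed(config$seed, "gibbs")
  fit <- fit_stability_lmm(averaged, config$scaling, mc)
  verdict <- classify_fitted_cost(fit)

  structure(
    list(calibration = attr(params, "calibration"),
         params = params,
         ess = ess,
         current_state = st,
         path_peak_x1 = curve$peak_x1,
         table = table,
         repeatability = rep_tab,
         coefficients = tidy(fit),
         converged = all(tidy(fit)$rhat < 1.2),
         verdict = verdict,
         fit = fit,
         seed = config$seed),
    class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  ESS morph: %g mm elongation, wings = %s (tilt %.2f deg)\n",
              x$ess$tail_elongation_mm[1], x$ess$wings[1], x$ess$tilt_deg[1]))
  cat(sprintf("  current state: (%.4f, %.4f); path peak at x1 = %.4f\n",
              x$current_state$x1_star, x$current_state$x2_star, x$path_peak_x1))
  cat(sprintf("  repeatability: r = %.4f (F = %.2f on %d, %d df)\n",
              x$repeatability$r, x$repeatability$F,
              x$repeatability$df_between, x$repeatability$df_within))
  cat(sprintf("  verdict: %s (Pr concave = %.3f); all Rhat < 1.2: %s\n",
              x$verdict$verdict, x$verdict$p_concave, x$converged))
  print(as.data.frame(x$coefficients), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' @param report A [run_pipeline()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  out <- list(
    seed = report$seed,
    ess = as.list(report$ess[1, ]),
    calibration = report$calibration,
    current_state = as.list(report$current_state),
    path_peak_x1 = report$path_peak_x1,
    repeatability = as.list(report$repeatability),
    coefficients = report$coefficients,
    converged = report$converged,
    verdict = as.list(report$verdict))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
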