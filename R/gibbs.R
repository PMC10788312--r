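#' MCMC configuration for the random-intercept sampler
#'
#' Defaults mirror the settings commonly used for animal-model style
#' Gibbs samplers in quantitative genetics: 13000 iterations with a 3000
#' iteration burn-in thinned by 10 (1000 retained draws per chain), an
#' effectively flat normal prior on fixed effects (variance 1e10), and
#' weak inverse-gamma priors on both variance components parameterised as
#' (V = 1, nu = 0.002), i.e. IG(shape = nu/2, rate = nu V/2). Three
#' chains are run by default so the potential scale reduction factor is
#' well defined.
#'
#' @param n_iter Total iterations per chain.
#' @param burn_in Discarded initial iterations (< `n_iter`).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param n_chains Number of chains (>= 2 for [rhat()]).
#' @param seed Integer seed; chain c uses `seed + c - 1`.
#' @param prior_fixed_var Prior variance of fixed effects.
#' @param prior_V,prior_nu Inverse-gamma hyperparameters for both
#'   variance components.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 13000, burn_in = 3000, thin = 10,
                        n_chains = 3, seed = 1,
                        prior_fixed_var = 1e10,
                        prior_V = 1, prior_nu = 0.002) {
  cfg <- list(n_iter = n_iter, burn_in = burn_in, thin = thin,
              n_chains = n_chains, seed = seed,
              prior_fixed_var = prior_fixed_var,
              prior_V = prior_V, prior_nu = prior_nu)
  for (nm in names(cfg)) check_scalar(cfg[[nm]], nm)
  if (burn_in >= n_iter) abort("`burn_in` must be < `n_iter`.",
                               class = "ornacost_invalid_input")
  if (thin < 1) abort("`thin` must be >= 1.", class = "ornacost_invalid_input")
  if (prior_fixed_var <= 0 || prior_V <= 0 || prior_nu <= 0) {
    abort("Prior parameters must be > 0.", class = "ornacost_invalid_input")
  }
  structure(cfg, class = "mcmc_config")
}

#' Gibbs sampler for the Gaussian random-intercept mixed model
#'
#' Samples the model \eqn{y = X\beta + u_{g} + e}, \eqn{u_j \sim N(0,
#' \sigma^2_u)}, \eqn{e \sim N(0, \sigma^2_e)} by cycling the standard
#' conjugate full conditionals: a multivariate-normal update for
#' \eqn{\beta}, independent normal updates for the group intercepts, and
#' inverse-gamma updates for both variances. Deterministic given the
#' seed: the same config reproduces the draws exactly.
#'
#' @param y Numeric response.
#' @param X Fixed-effect design matrix, full column rank.
#' @param groups Factor (or coercible) of group labels, >= 2 levels.
#' @param config An [mcmc_config()].
#' @return A list of per-chain matrices of retained draws; columns are
#'   the fixed effects (named after `X`'s columns), `var_individual`,
#'   `var_residual`.
#' @export
gibbs_lmm <- function(y, X, groups, config = mcmc_config()) {
  stopifnot(inherits(config, "mcmc_config"))
  X <- as.matrix(X)
  check_finite_vec(y, "y")
  g <- factor(groups)
  if (nlevels(g) < 2) abort("Need >= 2 groups.", class = "ornacost_invalid_input")
  if (length(y) != nrow(X) || length(y) != length(g)) {
    abort("`y`, `X` and `groups` must have matching lengths.",
          class = "ornacost_invalid_input")
  }
  p <- ncol(X)
  if (qr(X)$rank < p) abort("`X` is rank deficient.",
                            class = "ornacost_rank_deficient")
  cn <- colnames(X) %||% paste0("b", seq_len(p))
  lapply(seq_len(config$n_chains), function(chain) {
    run_gibbs_chain(y, X, g, config,
                    seed = as.integer(config$seed) + chain - 1L,
                    par_names = cn)
  })
}

run_gibbs_chain <- function(y, X, g, config, seed, par_names) {
  set.seed(seed)
  n <- length(y); p <- ncol(X); q <- nlevels(g)
  gi <- as.integer(g)
  n_j <- tabulate(gi, q)
  XtX <- crossprod(X)
  nu <- config$prior_nu; V0 <- config$prior_V
  prior_prec <- diag(1 / config$prior_fixed_var, p)

  # initial values from OLS
  beta <- stats::lm.fit(X, y)$coefficients
  beta[!is.finite(beta)] <- 0
  u <- rep(0, q)
  s2e <- max(stats::var(y - X %*% beta), 1e-6)
  s2u <- max(s2e / 2, 1e-6)

  keep_at <- seq(config$burn_in + config$thin, config$n_iter, by = config$thin)
  draws <- matrix(NA_real_, length(keep_at), p + 2)
  colnames(draws) <- c(par_names, "var_individual", "var_residual")
  k <- 1L

  for (it in seq_len(config$n_iter)) {
    # beta | u, variances
    prec <- XtX / s2e + prior_prec
    ch <- tryCatch(chol(prec), error = function(e) {
      abort(sprintf("Non-positive-definite conditional covariance at iteration %d.", it),
            class = "ornacost_numerical_failure")
    })
    rhs <- crossprod(X, y - u[gi]) / s2e
    mu <- backsolve(ch, forwardsolve(t(ch), rhs))
    beta <- mu + backsolve(ch, stats::rnorm(p))

    # group intercepts | beta, variances
    r <- y - as.vector(X %*% beta)
    sums <- as.vector(rowsum(r, gi, reorder = TRUE))
    v_j <- 1 / (n_j / s2e + 1 / s2u)
    u <- stats::rnorm(q, v_j * sums / s2e, sqrt(v_j))

    # variance components | rest
    s2u <- 1 / stats::rgamma(1, (q + nu) / 2, rate = (sum(u^2) + nu * V0) / 2)
    e <- r - u[gi]
    s2e <- 1 / stats::rgamma(1, (n + nu) / 2, rate = (sum(e^2) + nu * V0) / 2)

    if (k <= length(keep_at) && it == keep_at[k]) {
      draws[k, ] <- c(beta, s2u, s2e)
      k <- k + 1L
    }
  }
  draws
}

#' Potential scale reduction factor (Rhat)
#'
#' The Brooks--Gelman--Rubin diagnostic computed per parameter from the
#' between-chain variance \eqn{B} and mean within-chain variance
#' \eqn{W}: \eqn{\hat R = \sqrt{((n-1)/n \cdot W + B/n)/W}}. Values near
#' 1 indicate the chains have mixed; the conventional threshold used
#' throughout this package is 1.2.
#'
#' @param chains List of >= 2 draw matrices with identical dimensions and
#'   column names (as returned by [gibbs_lmm()]).
#' @return Named numeric vector of Rhat values.
#' @export
rhat <- function(chains) {
  if (!is.list(chains) || length(chains) < 2) {
    abort("Rhat needs >= 2 chains.", class = "ornacost_invalid_input")
  }
  n <- nrow(chains[[1]])
  if (n < 10 || !all(vapply(chains, nrow, 0L) == n)) {
    abort("Chains must have equal length >= 10.",
          class = "ornacost_invalid_input")
  }
  means <- vapply(chains, colMeans, numeric(ncol(chains[[1]])))
  vars <- vapply(chains, function(m) apply(m, 2, stats::var),
                 numeric(ncol(chains[[1]])))
  if (is.null(dim(means))) {  # single-parameter chains
    means <- matrix(means, 1); vars <- matrix(vars, 1)
  }
  B <- n * apply(means, 1, stats::var)
  W <- rowMeans(vars)
  out <- sqrt(((n - 1) / n * W + B / n) / W)
  out[W == 0 & B == 0] <- 1
  stats::setNames(out, colnames(chains[[1]]))
}

#' Two-sided posterior tail probability (pMCMC)
#'
#' `2 * min(Pr(draw > 0), Pr(draw < 0))`, floored at `1/n_draws` (a
#' posterior cannot testify below its own resolution, so fully one-sided
#' draws report the floor, conventionally printed as "< 1/n").
#'
#' @param draws Numeric vector of >= 100 posterior draws of one parameter.
#' @return A single probability in (0, 1].
#' @export
p_mcmc <- function(draws) {
  check_finite_vec(draws, "draws")
  n <- length(draws)
  if (n < 100) abort("pMCMC needs >= 100 draws.",
                     class = "ornacost_invalid_input")
  p <- 2 * min(mean(draws > 0), mean(draws < 0))
  max(p, 1 / n)
}

#' Fit the Bayesian stability model to an averaged experiment table
#'
#' The full statistical stage: builds the scaled quadratic design with
#' [build_design()], runs [gibbs_lmm()], and summarises the pooled
#' post-burn-in draws into a coefficient table (posterior mean, 95%
#' credible interval, pMCMC for fixed effects, Rhat for everything).
#'
#' @inheritParams build_design
#' @param config An [mcmc_config()].
#' @return An object of class `stability_fit`; see [tidy.stability_fit()],
#'   [glance.stability_fit()], [classify_fitted_cost()] and
#'   [autoplot.stability_fit()].
#' @export
fit_stability_lmm <- function(table, scaling = c("zscore", "center", "raw"),
                              config = mcmc_config()) {
  scaling <- match.arg(scaling)
  design <- build_design(table, scaling)
  chains <- gibbs_lmm(design$y, design$X, design$groups, config)
  pooled <- do.call(rbind, chains)
  rh <- if (length(chains) >= 2) rhat(chains) else
    stats::setNames(rep(NA_real_, ncol(pooled)), colnames(pooled))
  fixed <- colnames(design$X)
  summ <- tibble(
    term = colnames(pooled),
    estimate = colMeans(pooled),
    conf.low = apply(pooled, 2, stats::quantile, 0.025),
    conf.high = apply(pooled, 2, stats::quantile, 0.975),
    p_mcmc = ifelse(colnames(pooled) %in% fixed,
                    apply(pooled, 2, p_mcmc), NA_real_),
    rhat = as.numeric(rh[colnames(pooled)]))
  structure(
    list(summary = summ, chains = chains, design = design,
         config = config, data = tibble::as_tibble(table)),
    class = "stability_fit")
}

#' @export
print.stability_fit <- function(x, ...) {
  cat(sprintf("<stability_fit> %d obs, %d individuals, %d chains x %d draws\n",
              length(x$design$y), nlevels(x$design$groups),
              length(x$chains), nrow(x$chains[[1]])))
  print(as.data.frame(x$summary), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Tidy and glance methods for stability fits
#'
#' `tidy()` returns the per-parameter posterior summary (term, estimate,
#' 95% credible bounds, pMCMC for fixed effects, Rhat); `glance()` a
#' one-row model overview including the worst Rhat and whether all
#' parameters clear the 1.2 convergence threshold.
#'
#' @param x A [fit_stability_lmm()] object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy stability_fit
#' @export
tidy.stability_fit <- function(x, ...) x$summary

#' @rdname tidy.stability_fit
#' @method glance stability_fit
#' @export
glance.stability_fit <- function(x, ...) {
  tibble(n_obs = length(x$design$y),
         n_individuals = nlevels(x$design$groups),
         n_chains = length(x$chains),
         n_draws = length(x$chains) * nrow(x$chains[[1]]),
         max_rhat = max(x$summary$rhat),
         converged = max(x$summary$rhat) < 1.2)
}

#' Posterior verdict on the shape of the cost function
#'
#' On the angle scale a *convex* fitted curve (positive quadratic term
#' with its vertex inside the manipulated range) means stability first
#' improves and then worsens as the ornament is shortened — i.e. the
#' performance cost function is *concave*. Each posterior draw casts a
#' vote: the vertex is \eqn{-b_{lin}/(2 b_{quad})} on the scaled
#' predictor axis, and the verdict is `concave_cost` if at least `prob`
#' of draws have a positive quadratic term and an interior vertex,
#' `incremental_cost` if at least `prob` have a non-positive quadratic
#' term or an exterior vertex, and `inconclusive` otherwise.
#'
#' @param fit A [fit_stability_lmm()] object (quadratic model).
#' @param range Range of the scaled manipulation predictor; defaults to
#'   the fitted design's range.
#' @param prob Posterior mass required for a definite verdict.
#' @return A one-row tibble: `verdict`, `p_concave`, `p_incremental`.
#' @export
classify_fitted_cost <- function(fit, range = NULL, prob = 0.95) {
  stopifnot(inherits(fit, "stability_fit"))
  pooled <- do.call(rbind, fit$chains)
  if (!all(c("linear", "quadratic") %in% colnames(pooled))) {
    abort("Fit lacks linear/quadratic draws.", class = "ornacost_invalid_input")
  }
  range <- range %||% fit$design$z_range
  b1 <- pooled[, "linear"]; b2 <- pooled[, "quadratic"]
  vertex <- -b1 / (2 * b2)
  concave_vote <- b2 > 0 & vertex > range[1] & vertex < range[2]
  p_con <- mean(concave_vote)
  p_inc <- mean(!concave_vote)
  verdict <- if (p_con >= prob) "concave_cost"
  else if (p_inc >= prob) "incremental_cost"
  else "inconclusive"
  tibble(verdict = verdict, p_concave = p_con, p_incremental = p_inc)
}
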