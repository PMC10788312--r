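# Shared fixtures and independent oracles.

fig3_surface <- function() performance_surface(-8, -8, 7)

# brute-force 1-D maximizer: dense grid, then golden-section polish
grid_argmax_1d <- function(f, lower, upper, step = 1e-3) {
  xs <- seq(lower, upper, by = step)
  x0 <- xs[which.max(vapply(xs, f, 0))]
  opt <- stats::optimize(f, c(max(lower, x0 - 2 * step),
                              min(upper, x0 + 2 * step)),
                         maximum = TRUE, tol = 1e-10)
  opt$maximum
}

# brute-force 2-D maximizer: coarse grid then Nelder-Mead refinement
grid_argmax_2d <- function(f, xlim, ylim, n = 201) {
  xs <- seq(xlim[1], xlim[2], length.out = n)
  ys <- seq(ylim[1], ylim[2], length.out = n)
  vals <- outer(xs, ys, Vectorize(function(x, y) f(x, y)))
  ij <- which(vals == max(vals), arr.ind = TRUE)[1, ]
  start <- c(xs[ij[1]], ys[ij[2]])
  opt <- stats::optim(start, function(p) -f(p[1], p[2]),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$par
}

# random surface in the compensation regime (elliptical, gamma12 > 0)
random_regime_surface <- function() {
  g11 <- stats::runif(1, -10, -0.5)
  g22 <- stats::runif(1, -10, -0.5)
  g12 <- stats::runif(1, 0.05, 0.95) * sqrt(g11 * g22)
  performance_surface(g11, g22, g12)
}

# short MCMC settings for tests that only need a rough posterior
quick_config <- function(seed = 1, n_chains = 2) {
  mcmc_config(n_iter = 2500, burn_in = 500, thin = 2,
              n_chains = n_chains, seed = seed)
}

# batch-means Monte Carlo standard error, robust to autocorrelation;
# `chains` is a list of draw matrices, `par` a column name
mcse_batch <- function(chains, par, n_batch = 25) {
  bm <- unlist(lapply(chains, function(m) {
    x <- m[, par]
    n <- (length(x) %/% n_batch) * n_batch
    colMeans(matrix(x[seq_len(n)], ncol = n_batch))
  }))
  stats::sd(bm) / sqrt(length(bm))
}

# simulate straight from the random-intercept quadratic model
simulate_lmm <- function(beta, var_id, var_res, n_individuals,
                         z_levels = c(0, -20, -40, -60, -80)) {
  lev <- sort(unique(z_levels))
  z <- (z_levels - mean(lev)) / stats::sd(lev)
  d <- tidyr::expand_grid(individual_id = factor(seq_len(n_individuals)),
                          z = z)
  u <- stats::rnorm(n_individuals, 0, sqrt(var_id))
  d$y <- beta[1] + beta[2] * d$z + beta[3] * d$z^2 +
    u[as.integer(d$individual_id)] +
    stats::rnorm(nrow(d), 0, sqrt(var_res))
  d
}
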