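test_that("the sampler recovers known coefficients from simulated data", {
  set.seed(31)
  d <- simulate_lmm(beta = c(20, 1, 8), var_id = 0.2, var_res = 15,
                    n_individuals = 20)
  X <- cbind(intercept = 1, linear = d$z, quadratic = d$z^2)
  chains <- gibbs_lmm(d$y, X, d$individual_id,
                      mcmc_config(n_chains = 2, seed = 31))
  pooled <- do.call(rbind, chains)
  for (j in 1:3) {
    post_mean <- mean(pooled[, j])
    post_sd <- stats::sd(pooled[, j])
    expect_lt(abs(post_mean - c(20, 1, 8)[j]), 3 * post_sd)
  }
})

test_that("a zero group variance concentrates the posterior near zero", {
  set.seed(32)
  d <- simulate_lmm(beta = c(20, 1, 8), var_id = 0, var_res = 15,
                    n_individuals = 12)
  X <- cbind(intercept = 1, linear = d$z, quadratic = d$z^2)
  pooled <- do.call(rbind, gibbs_lmm(d$y, X, d$individual_id,
                                     quick_config(seed = 32)))
  expect_lt(stats::quantile(pooled[, "var_individual"], 0.025),
            0.1 * mean(pooled[, "var_residual"]))
})

test_that("with a flat prior the intercept-only posterior mean is the grand mean", {
  set.seed(33)
  y <- stats::rnorm(60, 12, 2)
  g <- factor(rep(1:6, each = 10))
  pooled <- do.call(rbind,
                    gibbs_lmm(y, cbind(intercept = rep(1, 60)), g,
                              quick_config(seed = 33)))
  expect_equal(mean(pooled[, "intercept"]), mean(y),
               tolerance = 3 * stats::sd(pooled[, "intercept"]) /
                 sqrt(nrow(pooled) / 4))
})

test_that("posterior means agree with the mixed-model GLS oracle", {
  set.seed(34)
  d <- simulate_lmm(beta = c(22, 1, 8), var_id = 2, var_res = 15,
                    n_individuals = 12)
  X <- cbind(intercept = 1, linear = d$z, quadratic = d$z^2)
  chains <- gibbs_lmm(d$y, X, d$individual_id,
                      mcmc_config(n_iter = 53000, n_chains = 2, seed = 34))
  pooled <- do.call(rbind, chains)
  oracle <- lme4::fixef(lme4::lmer(y ~ z + I(z^2) + (1 | individual_id),
                                   data = d, REML = TRUE))
  for (j in c("intercept", "linear", "quadratic")) {
    expect_lt(abs(mean(pooled[, j]) - oracle[[which(j == colnames(X))]]),
              3 * mcse_batch(chains, j))
  }
})

test_that("identical seeds reproduce the draws exactly", {
  set.seed(35)
  d <- simulate_lmm(beta = c(20, 1, 8), var_id = 0.5, var_res = 10,
                    n_individuals = 6)
  X <- cbind(intercept = 1, linear = d$z, quadratic = d$z^2)
  c1 <- gibbs_lmm(d$y, X, d$individual_id, quick_config(seed = 9))
  c2 <- gibbs_lmm(d$y, X, d$individual_id, quick_config(seed = 9))
  expect_identical(c1, c2)
  expect_error(gibbs_lmm(d$y, cbind(X, X[, 2]), d$individual_id,
                         quick_config()),
               class = "ornacost_rank_deficient")
})

test_that("Rhat separates mixed from unmixed chains", {
  set.seed(36)
  m <- matrix(stats::rnorm(2000), 1000, 2,
              dimnames = list(NULL, c("a", "b")))
  expect_lte(max(rhat(list(m, m))), 1 + 1e-12)

  n <- 1000
  c1 <- matrix(stats::rnorm(n, 0, 1), ncol = 1)
  c2 <- matrix(stats::rnorm(n, 10, 1), ncol = 1)
  got <- rhat(list(c1, c2))
  W <- (stats::var(as.numeric(c1)) + stats::var(as.numeric(c2))) / 2
  B <- n * stats::var(c(mean(c1), mean(c2)))
  expect_equal(as.numeric(got), sqrt(((n - 1) / n * W + B / n) / W))
  expect_gt(got, 1.2)

  expect_error(rhat(list(m)), class = "ornacost_invalid_input")
  # longer chains mix better on the default problem
  d <- simulate_lmm(beta = c(20, 1, 8), var_id = 0.5, var_res = 10,
                    n_individuals = 6)
  X <- cbind(intercept = 1, linear = d$z, quadratic = d$z^2)
  short <- rhat(gibbs_lmm(d$y, X, d$individual_id,
                          mcmc_config(n_iter = 140, burn_in = 40, thin = 1,
                                      n_chains = 3, seed = 4)))
  long <- rhat(gibbs_lmm(d$y, X, d$individual_id,
                         mcmc_config(n_iter = 10040, burn_in = 40, thin = 1,
                                     n_chains = 3, seed = 4)))
  expect_lt(max(long), max(short) + 0.05)
})

test_that("pMCMC is the floored two-sided tail probability", {
  expect_equal(p_mcmc(rep(1, 1000)), 1 / 1000)
  expect_equal(p_mcmc(c(rep(1, 975), rep(-1, 25))), 0.05)
  set.seed(37)
  expect_gt(p_mcmc(stats::rnorm(10000)), 0.9)
  expect_error(p_mcmc(1:10), class = "ornacost_invalid_input")
})

test_that("the cost-shape verdict reads the posterior correctly", {
  # degenerate posterior: certain convex curve with interior vertex
  m <- matrix(rep(c(20, 1, 8, 0.2, 15), each = 100), 100,
              dimnames = list(NULL, c("intercept", "linear", "quadratic",
                                      "var_individual", "var_residual")))
  fake <- structure(list(chains = list(m, m),
                         design = list(z_range = c(-1.2649, 1.2649))),
                    class = "stability_fit")
  v <- classify_fitted_cost(fake)
  expect_equal(v$verdict, "concave_cost")
  expect_equal(v$p_concave, 1)

  # certain concave-down curve: never a concave cost
  m2 <- m; m2[, "quadratic"] <- -8
  fake2 <- structure(list(chains = list(m2, m2),
                          design = list(z_range = c(-1.2649, 1.2649))),
                     class = "stability_fit")
  expect_equal(classify_fitted_cost(fake2)$verdict, "incremental_cost")

  m3 <- m[, 1:2]
  fake3 <- structure(list(chains = list(m3, m3),
                          design = list(z_range = c(-1, 1))),
                     class = "stability_fit")
  expect_error(classify_fitted_cost(fake3), class = "ornacost_invalid_input")
})

test_that("flat data rarely earn a confident concave verdict", {
  # quadratic coefficient truly zero: the 0.95-mass rule should almost
  # never fire (type-I style check)
  set.seed(38)
  false_concave <- 0
  for (i in 1:100) {
    d <- simulate_lmm(beta = c(20, 1, 0), var_id = 0.2, var_res = 15,
                      n_individuals = 8)
    avg <- tibble::tibble(individual_id = d$individual_id,
                          treatment_mm = d$z, mean_angle_deg = abs(d$y))
    fit <- fit_stability_lmm(avg, "raw",
                             mcmc_config(n_iter = 1600, burn_in = 400,
                                         thin = 2, n_chains = 1,
                                         seed = 1000 + i))
    if (classify_fitted_cost(fit)$verdict == "concave_cost") {
      false_concave <- false_concave + 1
    }
  }
  expect_lte(false_concave / 100, 0.05)
})

test_that("fit_stability_lmm summarises draws coherently", {
  p <- calibrate_generator()
  avg <- average_replicates(generate_experiment(p, seed = 2))
  fit <- fit_stability_lmm(avg, config = quick_config(seed = 2))
  td <- tidy(fit)
  expect_equal(td$term, c("intercept", "linear", "quadratic",
                          "var_individual", "var_residual"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  expect_true(all(td$estimate[4:5] > 0))
  expect_true(all(is.na(td$p_mcmc[4:5])) && all(!is.na(td$p_mcmc[1:3])))
  gl <- glance(fit)
  expect_equal(gl$n_obs, 20)
  expect_equal(gl$n_individuals, 4)
  expect_equal(gl$converged, gl$max_rhat < 1.2)
})
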