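test_that("evaluate_performance reproduces the quadratic form", {
  surf <- fig3_surface()
  expect_equal(evaluate_performance(surf, 0, 0), 0)
  expect_equal(evaluate_performance(surf, 1, 1), -1)  # -4 - 4 + 7
  expect_equal(evaluate_performance(performance_surface(-2, 0, 0), 3, 0), -9)
  # general coefficients, vectorised
  s <- performance_surface(-3, -5, 2, beta1 = 1, beta2 = -2, alpha = 0.5)
  x1 <- c(0, 1, -2); x2 <- c(0, 2, 3)
  expect_equal(evaluate_performance(s, x1, x2),
               0.5 * -3 * x1^2 + 1 * x1 + 0.5 * -5 * x2^2 - 2 * x2 +
                 2 * x1 * x2 + 0.5)
  expect_error(evaluate_performance(s, Inf, 0), class = "ornacost_invalid_input")
  expect_error(performance_surface(NaN, -1, 0), class = "ornacost_invalid_input")
})

test_that("geometry classification separates peak, saddle and ridge", {
  expect_equal(classify_geometry(fig3_surface()), "elliptical_peak")  # 49 < 64
  expect_equal(classify_geometry(performance_surface(-2, -2, 3)), "saddle")
  expect_equal(classify_geometry(performance_surface(-2, -2, 2)),
               "perfect_compensation_ridge")
  expect_equal(classify_geometry(performance_surface(2, -2, 0)),
               "not_applicable")
  expect_true(in_compensation_regime(fig3_surface()))
  expect_false(in_compensation_regime(performance_surface(-2, -2, -1)))
})

test_that("ridge compensation maximises performance at fixed ornament", {
  surf <- fig3_surface()
  expect_equal(ridge_compensation(surf, 8), 7)
  oracle <- grid_argmax_1d(function(x2) evaluate_performance(surf, 8, x2),
                           -20, 20)
  expect_equal(ridge_compensation(surf, 8), oracle, tolerance = 1e-6)
  expect_equal(ridge_compensation(performance_surface(-2, -2, 0), 3), 0)
  expect_equal(ridge_compensation(performance_surface(-2, -2, 2), 5), 5)
  expect_error(ridge_compensation(performance_surface(-2, 1, 0), 1),
               class = "ornacost_no_interior_maximum")
})

test_that("conditional cost curve matches the parent surface and its peak", {
  surf <- fig3_surface()
  curve <- conditional_cost_curve(surf, 14 / 3)
  expect_equal(curve$peak_x1, 49 / 12)
  oracle <- grid_argmax_1d(function(x1) evaluate_performance(surf, x1, 14 / 3),
                           0, 10, step = 1e-4)
  expect_equal(curve$peak_x1, oracle, tolerance = 1e-6)

  expect_equal(conditional_cost_curve(performance_surface(-5, -1, 2), 0)$peak_x1, 0)
  expect_equal(conditional_cost_curve(performance_surface(-2, -3, -1), 3)$peak_x1,
               -1.5)
  expect_error(conditional_cost_curve(performance_surface(0, -1, 0), 1),
               class = "ornacost_degenerate_curve")
})

test_that("cost curve equals the surface sliced at x2 = k (200 random surfaces)", {
  set.seed(41)
  grid <- seq(-5, 10, length.out = 31)
  for (i in 1:200) {
    surf <- random_regime_surface()
    k <- stats::runif(1, 0, 8)
    curve <- conditional_cost_curve(surf, k)
    expect_equal(evaluate_cost_curve(curve, grid),
                 evaluate_performance(surf, grid, rep(k, length(grid))),
                 tolerance = 1e-9)
  }
})

test_that("closed-form peak matches brute-force maximization for random curves", {
  set.seed(42)
  for (i in 1:25) {
    surf <- random_regime_surface()
    k <- stats::runif(1, 0, 8)
    curve <- conditional_cost_curve(surf, k)
    oracle <- grid_argmax_1d(function(x1) evaluate_cost_curve(curve, x1),
                             -20, 20, step = 1e-3)
    expect_equal(curve$peak_x1, oracle, tolerance = 1e-6)
  }
})

test_that("regime surfaces always put the conditional peak at positive ornament", {
  set.seed(43)
  for (i in 1:200) {
    surf <- random_regime_surface()
    k <- stats::runif(1, 1e-6, 10)
    expect_gt(conditional_cost_curve(surf, k)$peak_x1, 0)
  }
})

test_that("cost shape classification covers concave, incremental, flat", {
  surf <- fig3_surface()
  curve <- conditional_cost_curve(surf, 14 / 3)
  expect_equal(classify_cost_shape(curve, 16 / 3), "concave")
  expect_equal(classify_cost_shape(conditional_cost_curve(surf, 0), 5),
               "incremental")
  flat <- structure(list(a = 0, b = 0, c = 1, k = 0, peak_x1 = NaN),
                    class = "cost_curve")
  expect_equal(classify_cost_shape(flat, 1), "flat")
  # peak beyond current value: reduction only hurts
  expect_equal(classify_cost_shape(curve, 2), "decreasing")
  expect_error(classify_cost_shape(curve, -1), class = "ornacost_invalid_input")
})

test_that("a perfectly compensating surface is flat along its ridge", {
  surf <- performance_surface(-2, -2, 2)  # = -(x1 - x2)^2
  x1 <- seq(0, 12, length.out = 50)
  perf <- evaluate_performance(surf, x1, ridge_compensation(surf, x1))
  expect_equal(max(perf) - min(perf), 0, tolerance = 1e-9)
})

test_that("cost tables report best-minus-performance with zero at the peak", {
  curve <- conditional_cost_curve(fig3_surface(), 14 / 3)
  tab <- cost_curve_table(curve, seq(0, 6, by = 0.5))
  expect_true(all(tab$cost >= 0))
  expect_equal(min(cost_curve_table(curve, curve$peak_x1)$cost), 0)
  expect_equal(tab$cost,
               evaluate_cost_curve(curve, curve$peak_x1) - tab$performance)
})

test_that("surfaces round-trip through YAML and JSON configs", {
  surf <- performance_surface(-8, -8, 7, beta1 = 0.5, beta2 = -1, alpha = 2)
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_surface(surf, path)
    expect_equal(read_surface(path), surf)
  }
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(gamma11 = -1), bad)
  expect_error(read_surface(bad), class = "ornacost_invalid_input")
})
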