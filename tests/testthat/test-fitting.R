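test_that("least-squares costs sum squared residuals", {
  th <- theta_single(0.1, -0.05, 0.02)
  y <- eval_single(th, 100)
  expect_equal(cost_single(th, y), 0)
  expect_equal(cost_single(c(0, 0, 1), c(0, 0)), 2)
  # check against an independent stride-by-stride accumulation
  withr::with_seed(2, {
    y2 <- stats::runif(30, -0.3, 0.3)
    f <- th["a"] * exp(th["b"] * (1:30)) + th["c"]
    manual <- 0
    for (n in 1:30) manual <- manual + (y2[n] - f[n])^2
    expect_equal(cost_single(th, y2), unname(manual))
  })
})

test_that("double-model penalties activate exactly at the documented slack", {
  y <- rep(0, 10)
  cfg <- fit_config()
  sse <- function(th) sum((y - eval_double(th, 10))^2)

  th_eq <- c(0.1, -0.05, 0.1, -0.05, 0)  # bf = bs
  expect_equal(cost_double(th_eq, y, cfg) - sse(th_eq), 1e-3)

  th_ok <- c(0.1, -0.05, 0.1, -0.051, 0)  # bf <= bs - delta
  expect_equal(cost_double(th_ok, y, cfg) - sse(th_ok), 0)

  th_amp <- c(1.0005, -0.2, 1.0005, -0.3, 0)  # as + af = 2.001
  expect_equal(cost_double(th_amp, y, cfg) - sse(th_amp), 1e-3,
               tolerance = 1e-9)
})

test_that("a noise-free single-exponential series is recovered essentially exactly", {
  th <- theta_single(0.1, -0.05, 0.02)
  y <- eval_single(th, 300)
  fit <- fit_exp(y, "single", quick_config(seed = 3))
  expect_lt(fit$sse, 1e-8)
  expect_equal(as.numeric(fit$theta), as.numeric(th), tolerance = 1e-3)
  expect_equal(fit$penalty_at_optimum, 0)
})

test_that("a constant series is fitted by a flat trend", {
  fit <- fit_exp(rep(0.3, 120), "single", quick_config(seed = 4))
  expect_lt(fit$sse, 1e-10)
  expect_equal(fitted(fit), rep(0.3, 120), tolerance = 1e-4)
})

test_that("fits are deterministic given the master seed", {
  y <- simulate_series(
    simulation_spec(theta_single(0.08, -0.03, 0.01), 0.006, 200, seed = 9))
  f1 <- fit_exp(y, "single", quick_config(seed = 11))
  f2 <- fit_exp(y, "single", quick_config(seed = 11))
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$sse, f2$sse)
  expect_identical(f1$restart_costs, f2$restart_costs)
})

test_that("the returned cost is the minimum over restarts and bound variants", {
  y <- simulate_series(default_specs()$deadaptation2, seed = 21)
  fit <- fit_exp(y, "double", quick_config(seed = 6))
  best_cost <- min(fit$restart_costs$cost)
  expect_equal(fit$sse + fit$penalty_at_optimum, best_cost,
               tolerance = 1e-12)
  expect_true(all(c("no", "yes") %in% fit$restart_costs$variant))
  expect_equal(nrow(fit$restart_costs), 4L)  # 2 variants x 2 restarts
})

test_that("penalties at the optimum respect the delta slack", {
  y <- simulate_series(default_specs()$adaptation1, seed = 22)
  fit <- fit_exp(y, "double", quick_config(seed = 8))
  expect_lte(fit$penalty_at_optimum, 1e-3)
  th <- as.numeric(fit$theta)
  expect_true(all(th >= fit$bounds$lower - 1e-12))
  expect_true(all(th <= fit$bounds$upper + 1e-12))
})

test_that("pinned bounds remove parameters from the search", {
  y <- c(-0.5, 0.1, 0.3, 0.2)
  fit <- pure_mean_fit(y)
  expect_equal(fit$p, 1L)
  expect_equal(as.numeric(fit$theta)[3], mean(y), tolerance = 1e-6)
  expect_equal(fit$s, stats::sd(y), tolerance = 1e-4)
})

test_that("too few strides for the free parameters is an error", {
  expect_error(fit_exp(c(0.1, 0.2, 0.0), "single", quick_config()),
               "cannot identify")
})

test_that("the double model never fits worse than the single model", {
  y <- simulate_series(
    simulation_spec(theta_single(0.1, -0.02, 0.02), 0.006, 400, seed = 31))
  fs <- fit_exp(y, "single", quick_config(seed = 12))
  fd <- fit_exp(y, "double", quick_config(seed = 12))
  expect_lte(fd$sse, fs$sse + 1e-6)
})
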