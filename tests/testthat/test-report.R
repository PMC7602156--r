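test_that("the automated workflow selects and reports a model end to end", {
  y <- simulate_series(default_specs()$deadaptation2, seed = 55)
  report <- run_fit(y, model = "auto", seed = 13,
                    config = quick_config(seed = 13))
  expect_s3_class(report, "run_report")
  expect_equal(report$model_used, report$aic$selected)
  expect_true(all(c("single", "double") %in% names(report$fits)))
  expect_s3_class(report$common_language, "common_language_table")
  expect_true("overshoot" %in% report$common_language$quantity)
  expect_false(report$warning_flags[["non_converged"]])
})

test_that("reports are byte-identical under the same seed and input", {
  y <- simulate_series(
    simulation_spec(theta_single(0.08, -0.03, 0.02), 0.006, 150, seed = 3))
  r1 <- run_fit(y, model = "single", seed = 5, config = quick_config(seed = 5))
  r2 <- run_fit(y, model = "single", seed = 5, config = quick_config(seed = 5))
  expect_identical(as.character(report_json(r1)),
                   as.character(report_json(r2)))
})

test_that("two-column CSV input is converted to symmetry before fitting", {
  path <- withr::local_tempfile(fileext = ".csv")
  n <- 150
  y <- eval_single(theta_single(0.1, -0.05, 0.02), n)
  # invert symmetry to step lengths with unit sum: lf = (1+y)/2
  utils::write.csv(data.frame(fast = (1 + y) / 2, slow = (1 - y) / 2),
                   path, row.names = FALSE)
  report <- run_fit(path, model = "single", config = quick_config(seed = 2))
  expect_equal(report$n, n)
  expect_lt(report$fits$single$sse, 1e-6)
})

test_that("report JSON writes undefined endpoints as the string UD", {
  y <- simulate_series(default_specs()$adaptation1, seed = 77)
  dir <- withr::local_tempdir()
  report <- run_fit(y, model = "double", seed = 7,
                    config = quick_config(seed = 7), output_dir = dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  parsed <- jsonlite::fromJSON(file.path(dir, "report.json"),
                               simplifyVector = FALSE)
  quantities <- vapply(parsed$common_language, `[[`, "", "quantity")
  init <- parsed$common_language[[which(quantities == "initial_asymmetry")]]
  expect_identical(init$profile$lower, "UD")
  expect_true(is.numeric(init$linearized$lower) ||
                identical(init$linearized$lower, "UD"))
  # diagnostics CSVs alongside
  expect_length(report$files, 4L)
  expect_true(all(file.exists(report$files)))
})

test_that("the common-language table transforms rate intervals to stride counts", {
  y <- simulate_series(
    simulation_spec(theta_single(0.1, -0.02, 0.02), 0.005, 400, seed = 41))
  fit <- fit_exp(y, "single", quick_config(seed = 41))
  tab <- common_language_table(fit, y)
  row <- tab[tab$quantity == "half_change_strides", ]
  b_ci <- ci_profile(fit, y, "b")
  expect_equal(row$prof_lower, as.numeric(half_change_strides(b_ci$lower)))
  expect_equal(row$prof_upper, as.numeric(half_change_strides(b_ci$upper)))
  expect_true(row$prof_lower <= row$estimate &&
                row$estimate <= row$prof_upper)
})

test_that("simulation subcommand writes the configured series", {
  path <- withr::local_tempfile(fileext = ".csv")
  run_simulate("adaptation1", path)
  y <- read_series(path)
  expect_equal(length(y), 750L)
  # the seed flag overrides the spec seed
  path2 <- withr::local_tempfile(fileext = ".csv")
  run_simulate("adaptation1", path2, seed = 999)
  expect_false(identical(read_series(path2)$values, y$values))
  expect_error(run_simulate("nope", path), "unknown default spec")
})
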