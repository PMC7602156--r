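test_that("single exponential trend evaluates a*exp(b*n) + c", {
  expect_equal(eval_single(theta_single(0, -0.3, 0.3), 5), rep(0.3, 5))
  expect_equal(eval_single(theta_single(1, 0, 0), 4), rep(1, 4))
  expect_equal(eval_single(theta_single(1, -log(2), 0), 1), 0.5)
  expect_equal(eval_single(c(1, -log(2), 0), c(1, 2, 3)),
               c(0.5, 0.25, 0.125))
})

test_that("double trend reduces to the single trend when one amplitude is zero", {
  expect_equal(eval_double(theta_double(0, -0.1, 0, -0.2, 0), 10),
               rep(0, 10))
  withr::with_seed(7, {
    for (i in 1:10) {
      a <- stats::runif(1, -1, 1); b <- -stats::runif(1, 1e-3, log(2))
      cc <- stats::runif(1, -0.5, 0.5)
      expect_identical(eval_double(c(a, b, 0, -0.5, cc), 50),
                       eval_single(c(a, b, cc), 50))
    }
  })
})

test_that("overshoot requires opposite-sign amplitudes", {
  expect_false(overshoot(theta_double(0.5, -0.01, 0.5, -0.1, 0))$defined)
  expect_false(overshoot(theta_double(-0.5, -0.01, -0.5, -0.1, 0))$defined)
  expect_false(overshoot(theta_double(0, -0.01, -0.5, -0.1, 0))$defined)
  eq <- overshoot(theta_double(0.5, -0.05, -0.5, -0.05, 0))
  expect_false(eq$defined)
  expect_match(eq$note, "equal rate")
})

test_that("the critical-stride formula matches dense-grid extremisation", {
  # frozen worked example (verified against the grid oracle below)
  os <- overshoot(theta_double(0.5, -0.01, -0.5, -0.1, 0))
  expect_true(os$defined)
  expect_equal(os$ncrit, 25.584, tolerance = 1e-4)
  expect_equal(os$ycrit, 0.3484, tolerance = 1e-4)
  flip <- overshoot(theta_double(-0.5, -0.01, 0.5, -0.1, 0))
  expect_equal(flip$ycrit, -os$ycrit)

  withr::with_seed(42, {
    for (i in 1:50) {
      th <- random_overshoot_theta()
      os <- overshoot(th)
      oracle <- grid_extremum(th)
      expect_true(os$defined)
      expect_equal(os$ycrit, oracle$ycrit, tolerance = 1e-9)
    }
  })
})

test_that("the overshoot is flagged unobservable outside the stride range", {
  th <- theta_double(0.5, -0.01, -0.5, -0.1, 0)  # ncrit ~ 25.6
  expect_true(overshoot(th, n_max = 100)$observable)
  expect_false(overshoot(th, n_max = 10)$observable)
})

test_that("half-change stride counts floor ln2 over the rate magnitude", {
  expect_equal(half_change_strides(-log(2)), 1L)
  expect_equal(half_change_strides(-0.01), 69L)
  expect_error(half_change_strides(0.1), "rate < 0")
  expect_error(half_change_strides(0), "rate < 0")
  rates <- -seq(0.005, 0.6, length.out = 40)
  counts <- half_change_strides(rates)
  expect_true(all(diff(counts) <= 0))  # nonincreasing in |rate|
})

test_that("common-language transform maps parameters to practitioner quantities", {
  cl <- to_common_language(theta_single(0.1, -log(2), 0.02),
                           residual_sd = 0.006)
  expect_equal(cl$initial_asymmetry, 0.12)
  expect_equal(cl$total_change, 0.1)
  expect_equal(as.numeric(cl$half_change_strides), 1L)
  expect_equal(cl$final_asymmetry, 0.02)
  expect_false(cl$overshoot$defined)
  expect_equal(cl$residual_sd, 0.006)

  deg <- to_common_language(theta_double(0, -0.01, 0, -0.1, 0.05))
  expect_equal(deg$initial_asymmetry, 0.05)
  expect_equal(deg$total_change, 0)
  expect_false(deg$overshoot$defined)
  expect_true(deg$degenerate)

  dbl <- to_common_language(theta_double(0.5, -0.01, -0.5, -0.1, 0),
                            n_max = 750)
  expect_true(dbl$overshoot$defined)
  expect_equal(as.numeric(dbl$half_change_strides),
               c(half_change_strides(-0.01), half_change_strides(-0.1)))
})

test_that("overshoot map enumerates the admissible grid", {
  pos_only <- overshoot_map(as_values = seq(0.1, 1, 0.1),
                            af_values = seq(0.1, 1, 0.1))
  expect_true(all(!pos_only$defined))

  full <- overshoot_map()
  expect_true(all(full$bf < full$bs))
  expect_true(all(abs(full$as + full$af) <= 2))
  defined <- full[full$defined, ]
  expect_gt(nrow(defined), 0)
  expect_true(all(sign(defined$as * defined$af) == -1))
  # overshoots at non-negative critical strides stay within the
  # symmetry range; extrema extrapolated to ncrit < 0 may not
  observable <- defined[defined$ncrit >= 0, ]
  expect_true(all(observable$ycrit >= -1 & observable$ycrit <= 1))
  # and the achievable overshoot range spans a wide band of [-1, 1]
  expect_gt(max(observable$ycrit), 0.8)
  expect_lt(min(observable$ycrit), -0.8)

  one <- overshoot_map(as_values = 0.5, af_values = -0.5,
                       bs_values = -0.01, bf_values = -0.1)
  expect_equal(one$ycrit, 0.3484, tolerance = 1e-4)

  expect_error(overshoot_map(as_values = 0.5, af_values = 0.5,
                             bs_values = -0.1, bf_values = -0.01),
               "no admissible")
})
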