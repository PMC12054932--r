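test_that("c4 factor matches the closed Gamma form and its limits", {
  expect_equal(c4_factor(2), sqrt(2 / pi), tolerance = 1e-12)
  # frozen from the closed form, cross-checked against the mean sample SD of
  # 2e5 standard-normal samples (agreement to ~5e-4)
  expect_equal(c4_factor(10), 0.97266, tolerance = 1e-4)
  expect_equal(c4_factor(1e6), 1, tolerance = 1e-6)
  n <- 2:60
  expect_true(all(diff(c4_factor(n)) > 0))
  expect_true(all(c4_factor(n) > 0 & c4_factor(n) <= 1))
  expect_error(c4_factor(1), "whole number")
})

test_that("marker spike derives proportional SD and dose-error term", {
  sp <- marker_spike(2, 9666, 671)
  expect_equal(sp$prop_sd, 671 / 9666)
  expect_equal(sp$dose_error_term, (671 / 9666)^2 / 2)
  expect_equal(marker_spike(3, 1000)$dose_error_term, 0)
  expect_error(marker_spike(0, 1000), ">= 1")
  expect_error(marker_spike(1, -5), ">")
})

test_that("calibration statistics populate mean, SD, corrected prop SD", {
  const <- calibration_stats(c(27, 27, 27))
  expect_equal(const$mean_per_fov, 27)
  expect_equal(const$sd_per_fov, 0)
  expect_equal(const$prop_sd, 0)

  two <- calibration_stats(c(2, 4))
  expect_equal(two$mean_per_fov, 3)
  expect_equal(two$sd_per_fov, sqrt(2), tolerance = 1e-10)
  expect_equal(two$prop_sd, sqrt(2) / (sqrt(2 / pi) * 3), tolerance = 1e-10)
  expect_equal(two$prop_sd, 0.590818, tolerance = 1e-6)

  expect_error(calibration_stats(c(0, 0, 0)), "no common specimens")
  expect_error(calibration_stats(7), "at least 2")
  expect_error(calibration_stats(c(1.5, 2)), "whole numbers")
})

test_that("corrected proportional SD is calibrated for Poisson scatter", {
  # 17 fields of view at density 27: E[prop_sd] ~ 1/sqrt(27); the c4
  # correction cancels in expectation (it scales E[s] back to sigma)
  set.seed(42)
  vals <- replicate(4000, calibration_stats(rpois(17, 27))$prop_sd)
  expect_equal(mean(vals), 1 / sqrt(27), tolerance = 0.02)
})

test_that("linear concentration reproduces the marked-flock estimator", {
  expect_equal(
    concentration_linear(linear_tally(100, 10), unit_spike(1000)), 10000)
  expect_message(
    z <- concentration_linear(linear_tally(0, 10), unit_spike(1000)),
    "zero targets")
  expect_equal(z, 0)
  expect_error(concentration_linear(linear_tally(10, 0), unit_spike(1000)),
               "no markers")
  # equal counts with an exactly known spike recover the spike total
  expect_equal(
    concentration_linear(linear_tally(482, 482), unit_spike(30000)), 30000)
})

test_that("linear concentration conserves c * V * n = x * N1 * Ybar1", {
  set.seed(7)
  for (i in 1:25) {
    x <- sample(1:2000, 1); n <- sample(1:500, 1)
    v <- runif(1, 0.1, 50); k <- runif(1, 100, 1e5)
    cc <- concentration_linear(linear_tally(x, n), marker_spike(1, k),
                               sample_spec(v))
    expect_equal(cc * v * n, x * k, tolerance = 1e-12)
  }
})

test_that("linear total error combines dose and Poisson terms", {
  expect_equal(error_linear(linear_tally(500, 500), unit_spike()),
               100 * sqrt(2 / 500), tolerance = 1e-12)
  sp <- marker_spike(1, 1000, sqrt(0.000218) * 1000)  # T = 0.000218
  expect_equal(error_linear(linear_tally(300, 100), sp),
               100 * sqrt(0.000218 + 1 / 300 + 1 / 100), tolerance = 1e-12)
  expect_equal(error_linear(linear_tally(300, 100), sp), 11.641,
               tolerance = 1e-4)
  # error floor: huge counts leave only the dose term
  expect_equal(error_linear(linear_tally(10^9, 10^9), sp),
               100 * sqrt(0.000218), tolerance = 1e-3)
  expect_error(error_linear(linear_tally(0, 5), unit_spike()), ">= 1")
})

test_that("linear effort counts transitions, targets and markers", {
  expect_equal(effort_linear(linear_tally(10, 5), 0, 10), 15)
  expect_equal(effort_linear(linear_tally(482, 482), 2, 27),
               2 * 482 / 27 + 964, tolerance = 1e-12)
  expect_equal(effort_linear(linear_tally(482, 482), 2, 27), 999.70,
               tolerance = 1e-4)
  expect_equal(effort_linear(linear_tally(100, 100), 2, 10, asym = 5), 620)
})

test_that("extrapolated common count projects the calibration mean", {
  cal <- calibration_stats(rep(27, 15))
  expect_equal(extrapolated_common_count(cal, fov_extrapolation(119, 1)),
               3213)
  expect_equal(extrapolated_common_count(cal, fov_extrapolation(17, 1)), 459)
})

test_that("FOVS concentration estimates the known population", {
  cal <- calibration_stats(rep(27, 15))
  expect_equal(
    concentration_fovs(cal, fov_extrapolation(119, 107), unit_spike(1000)),
    27 * 119 * 1000 / 107, tolerance = 1e-12)
  expect_equal(
    concentration_fovs(cal, fov_extrapolation(119, 107), unit_spike(1000)),
    30028.04, tolerance = 1e-6)
  # extrapolated common count equal to the rare count recovers the spike
  cal10 <- calibration_stats(rep(10, 5))
  expect_equal(
    concentration_fovs(cal10, fov_extrapolation(4, 40), unit_spike(5555)),
    5555)
  expect_error(
    concentration_fovs(cal, fov_extrapolation(10, 0), unit_spike()),
    "no rare specimens")
})

test_that("role swap inverts the concentration against the spike total", {
  # counting targets per marker then inverting = counting markers per target
  counts <- c(24, 31, 27, 25, 29)
  k <- 1000
  c_t <- concentration_fovs(calibration_stats(counts, "targets_common"),
                            fov_extrapolation(50, 46), unit_spike(k))
  c_m <- concentration_fovs(calibration_stats(counts, "markers_common"),
                            fov_extrapolation(50, 46), unit_spike(k))
  expect_equal(c_t * c_m, k^2, tolerance = 1e-10)
})

test_that("FOVS total error combines dose, calibration and rare terms", {
  cal0 <- calibration_stats(rep(27, 16))  # s3P = 0
  expect_equal(error_fovs(cal0, fov_extrapolation(50, 100), unit_spike()),
               10)
  # an analytic case: s3P = 0.1, N3C = 16, n = 400
  # 100 sqrt(0.1^2/16 + 1/400) = 5.5902
  target <- 100 * sqrt(0.1^2 / 16 + 1 / 400)
  cal <- calibration_stats(rep(27, 16))
  cal$prop_sd <- 0.1  # inject the analytic proportional SD
  expect_equal(error_fovs(cal, fov_extrapolation(50, 400), unit_spike()),
               target, tolerance = 1e-12)
  expect_equal(target, 5.5902, tolerance = 1e-4)
  expect_error(error_fovs(cal0, fov_extrapolation(10, 0), unit_spike()),
               "rare count")
})

test_that("FOVS effort covers both stages", {
  cal <- calibration_stats(rep(27, 17))
  expect_equal(effort_fovs(cal, fov_extrapolation(17, 459), 2), 986)
  expect_equal(effort_fovs(cal, fov_extrapolation(17, 459), 0),
               459 + 459)
  cal11 <- calibration_stats(rep(27, 11))  # 297 specimens over 11 FOVs
  expect_equal(effort_fovs(cal11, fov_extrapolation(283, 127), 2),
               2 * 11 + 297 + 2 * 283 + 127)
})

test_that("errors are invariant to sample size and spike scaling", {
  t1 <- linear_tally(300, 100)
  e1 <- error_linear(t1, unit_spike(1000))
  e2 <- error_linear(t1, unit_spike(7e6))
  expect_identical(e1, e2)
  cal <- calibration_stats(c(20, 30, 25, 27))
  ex <- fov_extrapolation(40, 37)
  expect_identical(error_fovs(cal, ex, unit_spike(10)),
                   error_fovs(cal, ex, unit_spike(1e6)))
})

test_that("one-call estimators assemble consistent results", {
  res <- estimate_linear(linear_tally(300, 100), unit_spike(1000),
                         sample_spec(2, "g"), omega = 2,
                         mean_targets_per_fov = 27)
  expect_s3_class(res, "concentration_result")
  expect_equal(res$concentration, 300 * 1000 / (100 * 2))
  expect_true(res$approx_ci[1] < res$concentration &&
                res$concentration < res$approx_ci[2])
  expect_equal(diff(res$approx_ci),
               2 * qnorm(0.975) * res$concentration * res$total_error_pct / 100,
               tolerance = 1e-10)
  fres <- estimate_fovs(calibration_stats(c(24, 31, 27, 25, 29)),
                        fov_extrapolation(119, 107), unit_spike(1000))
  expect_equal(fres$extrapolated_common, mean(c(24, 31, 27, 25, 29)) * 119)
  df <- as.data.frame(fres)
  expect_equal(df$method, "fovs")
  expect_output(print(res), "Linear-method")
})
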