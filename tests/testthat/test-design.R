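test_that("effort coefficient reflects transitions, targets and markers", {
  expect_equal(effort_coefficient(design_point(1e12, 27, omega = 0)), 1,
               tolerance = 1e-10)
  expect_equal(effort_coefficient(design_point(1, 27, 2)), 2 / 27 + 2,
               tolerance = 1e-12)
  expect_equal(effort_coefficient(design_point(60, 27, 2)), 1.09074,
               tolerance = 1e-5)
  # times the stopping count gives the scenario budget
  expect_equal(effort_coefficient(design_point(60, 27, 2)) * 917, 1000.2,
               tolerance = 1e-4)
})

test_that("linear error-effort curve follows the inverse square-root law", {
  dp <- design_point(3, 10, 2)
  expect_equal(error_vs_effort_linear(dp, 400),
               2 * error_vs_effort_linear(dp, 1600), tolerance = 1e-12)
  expect_equal(error_vs_effort_linear(design_point(1, 27, 2), 999.7),
               100 * sqrt(2 * 2.074074 / 999.7), tolerance = 1e-6)
  expect_error(error_vs_effort_linear(dp, 0), "> 0")
})

test_that("two-dimensional FOVS error surface and its symmetry", {
  dp <- design_point(1, 27, 2)
  expect_equal(error_fovs_two_dim(dp, 17, 17), 100 * sqrt(2 / 459),
               tolerance = 1e-12)
  # swapping (N3C, N3E/u) leaves the surface unchanged
  dp2 <- design_point(5, 27, 2)
  expect_equal(error_fovs_two_dim(dp2, 4, 5 * 9),
               error_fovs_two_dim(dp2, 9, 5 * 4), tolerance = 1e-12)
  # dose-error floor as both counts grow
  dpT <- design_point(2, 27, 2, dose_error = 4e-4)
  expect_equal(error_fovs_two_dim(dpT, 1e9, 1e9), 100 * sqrt(4e-4),
               tolerance = 1e-6)
})

test_that("budget inversion for extrapolation fields of view conserves effort", {
  dp <- design_point(1, 27, 2)
  expect_equal(n3e_from_effort(dp, (2 + 27) * 17, 17), 0)
  expect_equal(n3e_from_effort(dp, 1000, 17), (1000 - 493) / 29,
               tolerance = 1e-12)
  expect_error(n3e_from_effort(dp, 100, 17), "exhausts budget")
  set.seed(3)
  for (i in 1:50) {
    dpr <- design_point(runif(1, 1, 50), runif(1, 1, 60), runif(1, 0, 5))
    ef <- runif(1, 200, 3000)
    n3c <- runif(1, 2, ef / (dpr$omega + dpr$density) * 0.8)
    n3e <- n3e_from_effort(dpr, ef, n3c)
    # expected counts plug back into the effort model exactly
    recon <- (dpr$omega + dpr$density) * n3c +
      (dpr$omega + dpr$density / dpr$u_hat) * n3e
    expect_equal(recon, ef, tolerance = 1e-10)
  }
})

test_that("optimal allocation reproduces every published study scenario", {
  sc <- study_scenarios()
  for (i in seq_len(nrow(sc))) {
    dp <- design_point(sc$u[i], 27, 2)
    al <- optimal_allocation(dp, effort_coefficient(dp) * sc$x_stop[i])
    expect_equal(al$n3c, sc$n3c[i], info = paste("u =", sc$u[i]))
    expect_equal(al$n3e, sc$n3e[i], info = paste("u =", sc$u[i]))
    expect_equal(al$delta_star, al$n3e_star / al$n3c_star, tolerance = 1e-12)
    # effort conservation at the continuous optimum
    spent <- (2 + 27) * al$n3c_star + (2 + 27 / sc$u[i]) * al$n3e_star
    expect_equal(spent, al$effort, tolerance = 1e-10)
  }
  expect_error(optimal_allocation(design_point(1, 27, 2), 10), "too small")
})

test_that("optimal count ratio is 1 at equal abundance and grows as sqrt(u)", {
  expect_equal(delta_star(design_point(1, 5, 3)), 1, tolerance = 1e-14)
  expect_equal(delta_star(design_point(1, 27, 0.1)), 1, tolerance = 1e-14)
  d1 <- delta_star(design_point(1e4, 27, 2))
  d4 <- delta_star(design_point(4e4, 27, 2))
  expect_equal(d4 / d1, 2, tolerance = 1e-3)
})

test_that("collapsed FOVS error-effort curve matches the optimum exactly", {
  set.seed(11)
  for (i in 1:30) {
    dp <- design_point(runif(1, 1, 60), runif(1, 0.5, 60), runif(1, 0, 5),
                       runif(1, 0, 5e-4))
    ef <- runif(1, 300, 3000)
    al <- optimal_allocation(dp, ef)
    expect_equal(error_vs_effort_fovs(dp, ef),
                 error_fovs_two_dim(dp, al$n3c_star, al$n3e_star),
                 tolerance = 1e-12)
  }
  # frozen analytic point: u = 20, density 10, omega 2, 10 % error
  dp <- design_point(20, 10, 2)
  ef10 <- (2 * 10 + 2 * 21 + 2 * sqrt(12 * 50)) / (10 * 0.01)
  expect_equal(ef10, 1109.898, tolerance = 1e-6)
  expect_equal(error_vs_effort_fovs(dp, ef10), 10, tolerance = 1e-10)
})

test_that("planning inverses round-trip to ten decimal places", {
  set.seed(23)
  for (i in 1:40) {
    dp <- design_point(runif(1, 1, 60), runif(1, 0.5, 60), runif(1, 0, 5),
                       runif(1, 0, 4e-4))
    sig <- runif(1, 100 * sqrt(dp$dose_error) + 1, 25)
    expect_equal(error_vs_effort_linear(dp, effort_for_error_linear(dp, sig)),
                 sig, tolerance = 1e-10)
    expect_equal(error_vs_effort_fovs(dp, effort_for_error_fovs(dp, sig)),
                 sig, tolerance = 1e-10)
    al <- allocation_for_error(dp, sig)
    expect_equal(error_fovs_two_dim(dp, al$n3c_star, al$n3e_star), sig,
                 tolerance = 1e-10)
    expect_equal(al$n3e_star / al$n3c_star, delta_star(dp),
                 tolerance = 1e-10)
    # the implied budget equals the effort-for-error closed form
    expect_equal(al$effort, effort_for_error_fovs(dp, sig),
                 tolerance = 1e-10)
  }
})

test_that("targeted-precision effort for the linear method", {
  expect_equal(effort_for_error_linear(design_point(3, 10, 2), 10),
               613.3333, tolerance = 1e-6)
  # dose-error floor is unattainable
  dpT <- design_point(3, 10, 2, dose_error = 1e-4)
  expect_error(effort_for_error_linear(dpT, 1), "unattainable")
  expect_error(effort_for_error_linear(dpT, 100 * sqrt(1e-4)), "unattainable")
  # effort blows up as the target error approaches the floor
  expect_gt(effort_for_error_linear(dpT, 100 * sqrt(1e-4) + 1e-6), 1e9)
})

test_that("allocation for a target error matches the fixed-budget optimum", {
  dp <- design_point(30, 27, 2)
  sig <- error_vs_effort_fovs(dp, 1000)
  al <- allocation_for_error(dp, sig)
  expect_equal(al$n3c, 13)
  expect_equal(al$n3e, 219)
  expect_equal(al$effort, 1000, tolerance = 1e-10)
})

test_that("error ratio crosses one exactly at the critical density", {
  for (u in c(1.2, 2, 5, 30, 60)) {
    ystar <- critical_density(u, 2)
    for (e in c(200, 1000, 5000)) {
      for (T in c(0, 2e-4, 1e-3)) {
        dp <- design_point(u, ystar, 2, T)
        expect_equal(error_ratio(dp, e), 1, tolerance = 1e-10)
      }
    }
  }
  # near-equal abundances favour the linear method ...
  expect_lt(error_ratio(design_point(1, 27, 2), 1000), 1)
  # ... skewed ones favour field-of-view subsampling
  expect_gt(error_ratio(design_point(30, 27, 2), 1000), 1)
})

test_that("critical density matches the published dividing-line values", {
  expect_equal(signif(critical_density(1.2, 2), 3), 132)
  expect_equal(round(critical_density(1.5, 2), 2), 29.95)
  expect_equal(round(critical_density(2, 2), 2), 11.87)
  expect_equal(round(critical_density(60, 2), 4), 0.5888)
  ys <- sapply(seq(1.05, 100, by = 0.5), critical_density, omega = 2)
  expect_true(all(diff(ys) < 0))
  suppressMessages(expect_identical(critical_density(1, 2), Inf))
  expect_error(critical_density(0.5, 2), "reversed")
})

test_that("dividing-line closed form solves the quartic crossover equation", {
  for (u in c(1.05, 1.2, 2, 3, 10, 50, 100)) {
    y <- critical_density(u, 2)
    resid <- (u^2 - 1)^2 * y^2 - 4 * 2 * u^2 * (1 + u) * y - 4 * 4 * u^3
    expect_equal(resid / ((u^2 - 1)^2 * y^2), 0, tolerance = 1e-10)
  }
})

test_that("method determination follows the critical density strictly", {
  expect_equal(choose_method(design_point(2, 27, 2))$recommended, "fovs")
  expect_equal(choose_method(design_point(1.2, 27, 2))$recommended, "linear")
  suppressMessages(
    mc1 <- choose_method(design_point(1, 5, 2)))
  expect_equal(mc1$recommended, "linear")
  tie <- choose_method(design_point(2, critical_density(2, 2), 2))
  expect_true(tie$tie)
  expect_equal(tie$recommended, "linear")
  expect_equal(tie$error_ratio, 1, tolerance = 1e-10)
})

test_that("effort difference agrees in sign with the method choice", {
  expect_equal(effort_difference(design_point(2, critical_density(2, 2), 2),
                                 10), 0, tolerance = 1e-6)
  expect_lt(effort_difference(design_point(1, 27, 2), 10), 0)
  expect_gt(effort_difference(design_point(10, 10, 2), 10), 0)
  set.seed(5)
  for (i in 1:30) {
    dp <- design_point(runif(1, 1.01, 60), runif(1, 0.5, 60), runif(1, 0.1, 5))
    same <- sign(effort_difference(dp, 10)) ==
      (if (choose_method(dp)$recommended == "fovs") 1 else -1)
    expect_true(same || abs(effort_difference(dp, 10)) < 1e-8)
  }
})

test_that("role reversal is an involution and unlocks u < 1 designs", {
  dp <- design_point(0.5, 13.5, 2)
  sw <- reversed_role(dp)
  expect_equal(sw$u_hat, 2)
  expect_equal(sw$density, 27)
  expect_equal(sw$role, "markers_common")
  back <- reversed_role(sw)
  expect_equal(back[c("u_hat", "density", "omega", "dose_error", "role")],
               dp[c("u_hat", "density", "omega", "dose_error", "role")],
               tolerance = 1e-12)
  expect_error(optimal_allocation(dp, 1000), "reversed_role")
  expect_error(error_ratio(dp, 1000), "reversed_role")
  expect_s3_class(optimal_allocation(sw, 1000), "fov_allocation")
})
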