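#' One-call concentration estimates
#'
#' Convenience wrappers combining the concentration, total-error and effort
#' computations for a single sample into a `"concentration_result"`.
#' The confidence interval is a documented normal approximation,
#' `c * (1 +/- z * sigma/100)`, truncated below at zero; it is *not* the
#' parametric interval of the classical palynological literature.
#'
#' @param tally A [linear_tally()].
#' @param spike A [marker_spike()].
#' @param sample A [sample_spec()].
#' @param omega Field-of-view transition effort factor; non-negative.
#' @param mean_targets_per_fov Mean targets per field of view, used only for
#'   the linear effort model.
#' @param asym Effort asymmetry factor, `>= 1`.
#' @param conf_level Confidence level for the normal-approximation interval.
#' @return A `"concentration_result"`: list with `concentration`,
#'   `total_error_pct`, `effort`, `method`, `role`, `extrapolated_common`
#'   (FOVS only, otherwise `NA`), `approx_ci` (length-2 numeric) and
#'   `size_unit`.
#' @examples
#' estimate_linear(linear_tally(300, 100),
#'                 marker_spike(2, 9666, 671), sample_spec(2.1, "g"),
#'                 omega = 2, mean_targets_per_fov = 27)
#' @export
estimate_linear <- function(tally, spike, sample = sample_spec(),
                            omega = 2, mean_targets_per_fov,
                            asym = 1, conf_level = 0.95) {
  conc <- concentration_linear(tally, spike, sample)
  err <- error_linear(tally, spike)
  eff <- effort_linear(tally, omega, mean_targets_per_fov, asym)
  new_concentration_result(conc, err, eff, "linear", "targets_common",
                           NA_real_, conf_level, sample$size_unit)
}

#' @rdname estimate_linear
#' @param calib A [calibration_stats()].
#' @param extrap A [fov_extrapolation()].
#' @param fpc Finite-population correction for the calibration term
#'   (default 1).
#' @examples
#' estimate_fovs(calibration_stats(c(24, 31, 27, 25, 29)),
#'               fov_extrapolation(119, 107),
#'               marker_spike(1, 1000), omega = 2)
#' @export
estimate_fovs <- function(calib, extrap, spike, sample = sample_spec(),
                          omega = 2, asym = 1, fpc = 1, conf_level = 0.95) {
  conc <- concentration_fovs(calib, extrap, spike, sample)
  err <- error_fovs(calib, extrap, spike, fpc)
  eff <- effort_fovs(calib, extrap, omega, asym)
  new_concentration_result(conc, err, eff, "fovs", calib$role,
                           extrapolated_common_count(calib, extrap),
                           conf_level, sample$size_unit)
}

new_concentration_result <- function(conc, err, eff, method, role,
                                     xhat, conf_level, size_unit) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmax(0, conc * (1 + c(-1, 1) * z * err / 100))
  structure(
    list(concentration = conc, total_error_pct = err, effort = eff,
         method = method, role = role, extrapolated_common = xhat,
         approx_ci = ci, conf_level = conf_level, size_unit = size_unit),
    class = "concentration_result")
}

#' @export
print.concentration_result <- function(x, ...) {
  cat(sprintf("%s-method concentration estimate\n",
              if (x$method == "linear") "Linear" else "FOVS"))
  cat(sprintf("  concentration : %.4g specimens per %s\n",
              x$concentration, x$size_unit))
  cat(sprintf("  total error   : %.3f %%\n", x$total_error_pct))
  cat(sprintf("  %.0f%% CI (normal approx.): [%.4g, %.4g]\n",
              100 * x$conf_level, x$approx_ci[1], x$approx_ci[2]))
  cat(sprintf("  effort        : %.1f units\n", x$effort))
  if (!is.na(x$extrapolated_common))
    cat(sprintf("  extrapolated common count: %.1f\n", x$extrapolated_common))
  invisible(x)
}

#' @export
as.data.frame.concentration_result <- function(x, ...) {
  data.frame(method = x$method, role = x$role,
             concentration = x$concentration,
             total_error_pct = x$total_error_pct,
             ci_lower = x$approx_ci[1], ci_upper = x$approx_ci[2],
             effort = x$effort,
             extrapolated_common = x$extrapolated_common,
             size_unit = x$size_unit,
             stringsAsFactors = FALSE)
}
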