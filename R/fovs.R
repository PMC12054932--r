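#' Calibration-count statistics
#'
#' Stage one of the field-of-view subsampling (FOVS) method: the common
#' specimen type (usually the targets) is counted exhaustively in `N3C`
#' fields of view.  This returns the per-FOV mean `Ybar3`, the
#' Bessel-corrected SD `s3`, and the proportional SD
#' \deqn{s_{3P} = \frac{s_3}{c_4(N_{3C})\,\bar{Y}_3},}
#' where the [c4_factor()] correction removes the small-sample downward bias
#' of `s3`.
#'
#' @param per_fov_counts Integer vector of common-specimen counts, one per
#'   calibration field of view; length `>= 2`, not all zero.
#' @param role `"targets_common"` (default) or `"markers_common"`: which
#'   specimen type was the subject of the calibration counts.
#' @return An object of class `"fov_calibration"` with fields
#'   `per_fov_counts`, `n_fov`, `mean_per_fov`, `sd_per_fov`, `prop_sd`,
#'   `role`.
#' @examples
#' calibration_stats(c(24, 31, 27, 25, 29))
#' @export
calibration_stats <- function(per_fov_counts,
                              role = c("targets_common", "markers_common")) {
  role <- match.arg(role)
  if (!is.numeric(per_fov_counts) || length(per_fov_counts) < 2L)
    stop("at least 2 calibration fields of view are required", call. = FALSE)
  if (any(!is.finite(per_fov_counts)) || any(per_fov_counts < 0) ||
      any(per_fov_counts != round(per_fov_counts)))
    stop("per-FOV counts must be non-negative whole numbers", call. = FALSE)
  m <- mean(per_fov_counts)
  if (m == 0)
    stop("no common specimens observed in the calibration counts",
         call. = FALSE)
  n_fov <- length(per_fov_counts)
  s <- stats::sd(per_fov_counts)
  structure(
    list(per_fov_counts = as.integer(per_fov_counts),
         n_fov = n_fov,
         mean_per_fov = m,
         sd_per_fov = s,
         prop_sd = s / (c4_factor(n_fov) * m),
         role = role),
    class = "fov_calibration")
}

#' @export
print.fov_calibration <- function(x, ...) {
  cat(sprintf(
    "FOVS calibration (%s): N3C = %d, mean/FOV = %.3f, s3 = %.3f, s3P = %.4f\n",
    x$role, x$n_fov, x$mean_per_fov, x$sd_per_fov, x$prop_sd))
  invisible(x)
}

#' Extrapolation-count record
#'
#' Stage two of the FOVS method: a fresh set of `N3E` fields of view is
#' scanned, counting only the rare specimen type (usually the exotic
#' markers).
#'
#' @param n_fov Number of extrapolation-count fields of view (`N3E`);
#'   positive integer.
#' @param rare_count Total rare specimens counted across those fields of
#'   view; non-negative integer.
#' @return An object of class `"fov_extrapolation"`.
#' @examples
#' fov_extrapolation(n_fov = 119, rare_count = 107)
#' @export
fov_extrapolation <- function(n_fov, rare_count) {
  stopifnot_scalar(n_fov, "n_fov", 1)
  stopifnot_scalar(rare_count, "rare_count", 0)
  if (n_fov != round(n_fov) || rare_count != round(rare_count))
    stop("counts must be whole numbers", call. = FALSE)
  structure(list(n_fov = as.integer(n_fov),
                 rare_count = as.integer(rare_count)),
            class = "fov_extrapolation")
}

#' Extrapolated common-specimen count
#'
#' The implied number of common specimens in the extrapolation fields of
#' view, `xhat = Ybar3 * N3E`: the calibration mean projected over the area
#' actually scanned for rare specimens.
#'
#' @param calib A [calibration_stats()] object.
#' @param extrap A [fov_extrapolation()] from the same slide region.
#' @return The (real-valued) extrapolated count.
#' @examples
#' cal <- calibration_stats(rep(27, 15))
#' extrapolated_common_count(cal, fov_extrapolation(119, 107))  # 3213
#' @export
extrapolated_common_count <- function(calib, extrap) {
  stopifnot(inherits(calib, "fov_calibration"),
            inherits(extrap, "fov_extrapolation"))
  calib$mean_per_fov * extrap$n_fov
}

#' Concentration from a FOVS count
#'
#' With targets common, the extrapolated target count enters the numerator of
#' the marker-ratio estimator:
#' \deqn{c_{Fx} = \frac{\hat{x} \, N_1 \bar{Y}_1}{n \, \bar{V}},\qquad
#'       \hat{x} = \bar{Y}_{3x} N_{3E}.}
#' With markers common the roles swap by symmetry: the extrapolated *marker*
#' count `nhat = Ybar3n * N3E` forms the denominator and the directly counted
#' rare targets `x` the numerator.
#'
#' @inheritParams extrapolated_common_count
#' @param spike A [marker_spike()].
#' @param sample A [sample_spec()].
#' @return Concentration of targets per `size_unit`.
#' @examples
#' cal <- calibration_stats(rep(27, 15))
#' concentration_fovs(cal, fov_extrapolation(119, 107), marker_spike(1, 1000))
#' @export
concentration_fovs <- function(calib, extrap, spike, sample = sample_spec()) {
  stopifnot(inherits(calib, "fov_calibration"),
            inherits(extrap, "fov_extrapolation"),
            inherits(spike, "marker_spike"),
            inherits(sample, "sample_spec"))
  if (extrap$rare_count < 1)
    stop("no rare specimens counted: concentration undefined", call. = FALSE)
  common_hat <- extrapolated_common_count(calib, extrap)
  marker_total <- spike$n_doses * spike$mean_per_dose
  if (calib$role == "targets_common") {
    common_hat * marker_total / (extrap$rare_count * sample$total_size)
  } else {
    extrap$rare_count * marker_total / (common_hat * sample$total_size)
  }
}

#' Total standard error of a FOVS concentration
#'
#' \deqn{\sigma_F = 100\sqrt{T + s_{3P}^2/N_{3C} + 1/n}} (percent):
#' dose uncertainty, the standard error of the calibration mean (a
#' near-normal quantity by the central limit theorem), and Poisson scatter of
#' the rare count, which at the low per-FOV densities typical of rare
#' specimens is well approximated by `1/n`.
#'
#' @inheritParams concentration_fovs
#' @param fpc Optional finite-population correction factor in `[0, 1]`
#'   multiplying the calibration standard-error term (see [fpc_factor()]);
#'   default 1 (effectively infinite population, the usual case for real
#'   slides).
#' @return Total standard error in percent.
#' @examples
#' cal <- calibration_stats(c(24, 31, 27, 25, 29))
#' error_fovs(cal, fov_extrapolation(119, 107), marker_spike(1, 1000))
#' @export
error_fovs <- function(calib, extrap, spike, fpc = 1) {
  stopifnot(inherits(calib, "fov_calibration"),
            inherits(extrap, "fov_extrapolation"),
            inherits(spike, "marker_spike"))
  stopifnot_scalar(fpc, "fpc", 0)
  if (fpc > 1) stop("`fpc` must be in [0, 1]", call. = FALSE)
  if (extrap$rare_count < 1)
    stop("error undefined: rare count must be >= 1", call. = FALSE)
  100 * sqrt(spike$dose_error_term +
               (fpc * calib$prop_sd)^2 / calib$n_fov +
               1 / extrap$rare_count)
}

#' Data-collection effort of a FOVS count
#'
#' \deqn{e_F = \omega N_{3C} + a\,x + \omega N_{3E} + n:}
#' transitions plus specimen identifications for the calibration stage
#' (`x` = total common specimens counted there) and the extrapolation stage.
#'
#' @inheritParams error_fovs
#' @param omega Field-of-view transition effort factor; non-negative.
#' @param asym Effort asymmetry factor applied to the common-specimen
#'   identifications; `>= 1`, default 1.
#' @return Effort in specimen-count time units.
#' @examples
#' cal <- calibration_stats(rep(27, 17))
#' effort_fovs(cal, fov_extrapolation(17, 459), omega = 2)  # 986
#' @export
effort_fovs <- function(calib, extrap, omega, asym = 1) {
  stopifnot(inherits(calib, "fov_calibration"),
            inherits(extrap, "fov_extrapolation"))
  stopifnot_scalar(omega, "omega", 0)
  stopifnot_scalar(asym, "asym", 1)
  omega * calib$n_fov + asym * sum(calib$per_fov_counts) +
    omega * extrap$n_fov + extrap$rare_count
}
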