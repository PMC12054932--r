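#' Linear-method count tally
#'
#' A sequential joint count from one contiguous window: all targets (`x`) and
#' all exotic markers (`n`) encountered until a pre-set stopping count is
#' reached.  Under the stop rule `"fixed_targets"` the target count is the
#' pre-determined quantity and the marker count is random (and vice versa);
#' either way both Poisson error terms enter the total error, the fixed one
#' reflecting the random extent of the window.
#'
#' @param targets Number of target specimens counted (`x`); non-negative
#'   integer.
#' @param markers Number of marker specimens counted (`n`); non-negative
#'   integer.
#' @param stop_rule `"fixed_targets"` (default) or `"fixed_markers"`.
#' @return An object of class `"linear_tally"`.
#' @examples
#' linear_tally(targets = 100, markers = 10)
#' @export
linear_tally <- function(targets, markers,
                         stop_rule = c("fixed_targets", "fixed_markers")) {
  stop_rule <- match.arg(stop_rule)
  stopifnot_scalar(targets, "targets", 0)
  stopifnot_scalar(markers, "markers", 0)
  if (targets != round(targets) || markers != round(markers))
    stop("counts must be whole numbers", call. = FALSE)
  if (targets + markers < 1)
    stop("a tally must contain at least one specimen", call. = FALSE)
  structure(list(targets = targets, markers = markers, stop_rule = stop_rule),
            class = "linear_tally")
}

#' Concentration from a linear count
#'
#' The classical exotic-marker estimator
#' \deqn{c_L = \frac{x \, N_1 \, \bar{Y}_1}{n \, \bar{V}},}
#' the counted target-to-marker ratio scaled by the known marker total
#' `N1 * Ybar1` and the sample size `Vbar`.
#'
#' @param tally A [linear_tally()]; `markers` must be at least 1.
#' @param spike A [marker_spike()].
#' @param sample A [sample_spec()].
#' @return Concentration (targets per `size_unit`).
#' @examples
#' # 100 targets against 10 of 1000 introduced markers: population 10,000
#' concentration_linear(linear_tally(100, 10), marker_spike(1, 1000),
#'                      sample_spec(1))
#' @export
concentration_linear <- function(tally, spike, sample = sample_spec()) {
  stopifnot(inherits(tally, "linear_tally"), inherits(spike, "marker_spike"),
            inherits(sample, "sample_spec"))
  if (tally$markers < 1)
    stop("no markers counted: concentration unbounded", call. = FALSE)
  if (tally$targets == 0)
    message("zero targets counted: concentration estimate is 0")
  tally$targets * spike$n_doses * spike$mean_per_dose /
    (tally$markers * sample$total_size)
}

#' Total standard error of a linear-method concentration
#'
#' Propagates the three independent error sources — dose uncertainty,
#' Poisson scatter of the target count and Poisson scatter of the marker
#' count — as
#' \deqn{\sigma_L = 100 \sqrt{T + 1/x + 1/n}} (percent),
#' where `T = s1P^2 / N1` is the dose-error term of the spike.  `100 sqrt(T)`
#' is a hard floor: no amount of counting improves on the dose uncertainty.
#'
#' @inheritParams concentration_linear
#' @return Total standard error in percent.
#' @examples
#' error_linear(linear_tally(500, 500), marker_spike(1, 1000))  # 6.32 %
#' @export
error_linear <- function(tally, spike) {
  stopifnot(inherits(tally, "linear_tally"), inherits(spike, "marker_spike"))
  if (tally$targets < 1 || tally$markers < 1)
    stop("error undefined: both target and marker counts must be >= 1",
         call. = FALSE)
  100 * sqrt(spike$dose_error_term + 1 / tally$targets + 1 / tally$markers)
}

#' Data-collection effort of a linear count
#'
#' Effort is a time proxy: one unit per specimen identified plus `omega`
#' units per field-of-view transition,
#' \deqn{e_L = \omega \, x / \bar{Y}_{3x} + a\,x + n,}
#' where `Ybar3x` is the mean number of targets per field of view (so
#' `x / Ybar3x` approximates the number of fields of view traversed) and `a`
#' is an optional effort asymmetry factor for targets that take longer to
#' identify than markers (default 1: equal identification time).
#'
#' @inheritParams concentration_linear
#' @param omega Field-of-view transition effort factor (ratio of transition
#'   time to single-specimen count time); non-negative.
#' @param mean_targets_per_fov Mean targets per field of view (`Ybar3x`);
#'   positive.
#' @param asym Effort asymmetry factor applied to target identifications;
#'   `>= 1`, default 1.
#' @return Effort in specimen-count time units.
#' @examples
#' effort_linear(linear_tally(482, 482), omega = 2, mean_targets_per_fov = 27)
#' @export
effort_linear <- function(tally, omega, mean_targets_per_fov, asym = 1) {
  stopifnot(inherits(tally, "linear_tally"))
  stopifnot_scalar(omega, "omega", 0)
  stopifnot_scalar(mean_targets_per_fov, "mean_targets_per_fov", 0,
                   strict = TRUE)
  stopifnot_scalar(asym, "asym", 1)
  omega * tally$targets / mean_targets_per_fov +
    asym * tally$targets + tally$markers
}
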