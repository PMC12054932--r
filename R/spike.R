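#' Exotic marker spike metadata
#'
#' Describes the doses (e.g. *Lycopodium clavatum* tablets) of exotic markers
#' added to a sample: how many doses, the mean and standard deviation of
#' markers per dose.  Two derived quantities drive every error formula in the
#' package: the proportional dose SD `s1/Ybar1` and the dose-error term
#' `T = (s1/Ybar1)^2 / N1`, the variance contribution of dose uncertainty to
#' any concentration estimate.  Dose statistics are taken as supplied by the
#' producer; no small-sample correction is applied to them.
#'
#' @param n_doses Number of marker doses (tablets) added; positive integer.
#' @param mean_per_dose Mean number of markers per dose; positive.
#' @param sd_per_dose Standard deviation of markers per dose; non-negative.
#'   `0` (the default) models exactly known marker totals and gives a
#'   dose-error term of zero.
#'
#' @return An object of class `"marker_spike"`: a list with fields `n_doses`,
#'   `mean_per_dose`, `sd_per_dose`, `prop_sd` and `dose_error_term`.
#' @examples
#' spike <- marker_spike(n_doses = 2, mean_per_dose = 9666, sd_per_dose = 671)
#' spike$dose_error_term
#' @export
marker_spike <- function(n_doses, mean_per_dose, sd_per_dose = 0) {
  stopifnot_scalar(n_doses, "n_doses", 1)
  if (n_doses != round(n_doses))
    stop("`n_doses` must be a whole number", call. = FALSE)
  stopifnot_scalar(mean_per_dose, "mean_per_dose", 0, strict = TRUE)
  stopifnot_scalar(sd_per_dose, "sd_per_dose", 0)
  prop_sd <- sd_per_dose / mean_per_dose
  structure(
    list(n_doses = as.integer(n_doses),
         mean_per_dose = mean_per_dose,
         sd_per_dose = sd_per_dose,
         prop_sd = prop_sd,
         dose_error_term = prop_sd^2 / n_doses),
    class = "marker_spike")
}

#' @export
print.marker_spike <- function(x, ...) {
  cat(sprintf("Marker spike: %d dose(s) of %g +/- %g markers (T = %.3g)\n",
              x$n_doses, x$mean_per_dose, x$sd_per_dose, x$dose_error_term))
  invisible(x)
}

#' Sample size specification
#'
#' The total size of the sample the counts refer to (mass, area or volume).
#' Concentrations are reported per one `size_unit`.
#'
#' @param total_size Positive total sample size.
#' @param size_unit Unit label, e.g. `"g"`, `"mL"`, `"cm2"` or
#'   `"arbitrary"` (default).
#' @return An object of class `"sample_spec"`.
#' @examples
#' sample_spec(2.076, "g")
#' @export
sample_spec <- function(total_size = 1, size_unit = "arbitrary") {
  stopifnot_scalar(total_size, "total_size", 0, strict = TRUE)
  structure(list(total_size = total_size, size_unit = as.character(size_unit)),
            class = "sample_spec")
}
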