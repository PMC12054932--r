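#' Unbiasing factor for the sample standard deviation
#'
#' Under a normal model the sample standard deviation `s` (with Bessel's
#' correction) underestimates the population value; `E[s] = c4(n) * sigma`
#' with
#' \deqn{c_4(n) = \sqrt{2/(n-1)} \; \Gamma(n/2) / \Gamma((n-1)/2).}
#' Dividing `s` by `c4(n)` removes this bias.  The factor is strictly
#' increasing in `n` and tends to 1, so the correction matters only for the
#' small calibration counts typical of field-of-view work (e.g.
#' `c4(10) = 0.9727`).
#'
#' Computed on the log-Gamma scale so it is stable for any `n`.
#'
#' @param n Sample size(s), integer `>= 2` (vectorised).
#' @return `c4(n)`, in `(0, 1]`.
#' @examples
#' c4_factor(2)   # sqrt(2/pi)
#' c4_factor(17)
#' @export
c4_factor <- function(n) {
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 2) ||
      any(n != round(n)))
    stop("`n` must be whole number(s) >= 2", call. = FALSE)
  exp(0.5 * log(2 / (n - 1)) + lgamma(n / 2) - lgamma((n - 1) / 2))
}
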