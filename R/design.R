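#' Sampling-design point
#'
#' The four quantities that drive all closed-form planning calculations:
#' the common-to-rare specimen ratio `u_hat` (estimated as `x/n` for a linear
#' count or `Ybar3x/Ybar3n` for a FOVS count), the mean density of the common
#' specimen type per field of view, the field-of-view transition effort
#' factor `omega`, and the dose-error term `T` of the marker spike.
#'
#' The planning formulas are written for the orientation in which the
#' *common* specimens are counted in the calibration stage and
#' `u_hat >= 1`.  If markers outnumber targets (`u_hat < 1` with targets as
#' the common type), construct the point and pass it through
#' [reversed_role()] first; planning functions refuse `u_hat < 1`.
#'
#' @param u_hat Common-to-rare specimen ratio; positive.
#' @param density Mean number of common specimens per field of view
#'   (`Ybar3x`, or `Ybar3n` for a reversed-role point); positive.
#' @param omega Transition effort factor; non-negative. Default 2, typical of
#'   microscope work where a stage move costs about two specimen counts.
#' @param dose_error Dose-error term `T = s1P^2 / N1`; non-negative,
#'   default 0.
#' @param role Which specimen type is the common (calibration) one.
#' @return An object of class `"design_point"`.
#' @examples
#' design_point(u_hat = 10, density = 27)
#' @export
design_point <- function(u_hat, density, omega = 2, dose_error = 0,
                         role = c("targets_common", "markers_common")) {
  role <- match.arg(role)
  stopifnot_scalar(u_hat, "u_hat", 0, strict = TRUE)
  stopifnot_scalar(density, "density", 0, strict = TRUE)
  stopifnot_scalar(omega, "omega", 0)
  stopifnot_scalar(dose_error, "dose_error", 0)
  structure(list(u_hat = u_hat, density = density, omega = omega,
                 dose_error = dose_error, role = role),
            class = "design_point")
}

#' @export
print.design_point <- function(x, ...) {
  cat(sprintf(
    "Design point (%s): u_hat = %g, density = %g per FOV, omega = %g, T = %g\n",
    x$role, x$u_hat, x$density, x$omega, x$dose_error))
  invisible(x)
}

check_primal <- function(dp) {
  stopifnot(inherits(dp, "design_point"))
  if (dp$u_hat < 1)
    stop("u_hat < 1: the rare type is the common one in this orientation; ",
         "apply reversed_role() first", call. = FALSE)
  invisible(dp)
}

#' Swap the common and rare roles of a design point
#'
#' When the exotic markers outnumber the targets the calibration counts
#' should target the markers instead; by the symmetry of the two-stage
#' design, every planning formula then applies verbatim to the swapped
#' point: `u' = 1/u` and the density becomes that of the *other* specimen
#' type, `density' = density / u`.  Applying the swap twice returns the
#' original point.
#'
#' @param dp A [design_point()].
#' @return The role-swapped `"design_point"`.
#' @examples
#' dp <- design_point(u_hat = 0.5, density = 13.5)   # markers twice as common
#' reversed_role(dp)                                 # u' = 2, density 27
#' @export
reversed_role <- function(dp) {
  stopifnot(inherits(dp, "design_point"))
  design_point(1 / dp$u_hat, dp$density / dp$u_hat, dp$omega, dp$dose_error,
               role = if (dp$role == "targets_common") "markers_common"
                      else "targets_common")
}

#' Linear-method effort per specimen
#'
#' In a linear count the expected effort is proportional to the number of
#' common specimens counted: `eL = A x` with
#' \deqn{A = \omega/\bar{Y}_{3x} + 1 + 1/\hat{u}}
#' (transitions per target, the target itself, and the accompanying
#' markers).
#'
#' @param dp A [design_point()] with `u_hat >= 1`.
#' @return The effort coefficient `A`.
#' @examples
#' effort_coefficient(design_point(1, 27, omega = 2))  # 2.074; x 482 ~ 1000
#' @export
effort_coefficient <- function(dp) {
  check_primal(dp)
  dp$omega / dp$density + 1 + 1 / dp$u_hat
}

#' Linear-method error as a function of effort
#'
#' \deqn{\sigma_L(e_L) = 100\sqrt{T + (1+\hat{u})A/e_L},}
#' strictly decreasing in effort, with floor `100 sqrt(T)`.  Error falls with
#' the square root of effort: quadrupling the effort halves the error.
#'
#' @inheritParams effort_coefficient
#' @param effort Positive effort budget (specimen-count time units).
#' @return Predicted total standard error in percent.
#' @examples
#' error_vs_effort_linear(design_point(1, 27), effort = 999.7)
#' @export
error_vs_effort_linear <- function(dp, effort) {
  check_primal(dp)
  stopifnot_scalar(effort, "effort", 0, strict = TRUE)
  100 * sqrt(dp$dose_error +
               (1 + dp$u_hat) * effort_coefficient(dp) / effort)
}

#' FOVS error as a function of the two field-of-view counts
#'
#' The two-dimensional FOVS error surface under the Poisson approximation of
#' the calibration term:
#' \deqn{\sigma_F(N_{3C}, N_{3E}) =
#'   100\sqrt{T + \frac{1}{N_{3C}\bar{Y}_{3x}} +
#'            \frac{\hat{u}}{N_{3E}\bar{Y}_{3x}}}.}
#' Symmetric under the exchange `(N3C, N3E/u)`.
#'
#' @inheritParams effort_coefficient
#' @param n3c Calibration-count fields of view; positive (need not be
#'   integer for planning purposes).
#' @param n3e Extrapolation-count fields of view; positive.
#' @return Predicted total standard error in percent.
#' @examples
#' error_fovs_two_dim(design_point(1, 27), 17, 17)
#' @export
error_fovs_two_dim <- function(dp, n3c, n3e) {
  check_primal(dp)
  stopifnot_scalar(n3c, "n3c", 0, strict = TRUE)
  stopifnot_scalar(n3e, "n3e", 0, strict = TRUE)
  100 * sqrt(dp$dose_error + 1 / (n3c * dp$density) +
               dp$u_hat / (n3e * dp$density))
}

#' Extrapolation fields of view affordable after calibration
#'
#' Inverts the FOVS effort model at its expected counts: with a budget `eF`
#' and `n3c` calibration fields of view already committed,
#' \deqn{N_{3E} = \frac{e_F - (\omega + \bar{Y}_{3x})N_{3C}}
#'                     {\omega + \bar{Y}_{3x}/\hat{u}}.}
#'
#' @inheritParams error_vs_effort_linear
#' @param n3c Calibration fields of view already planned.
#' @return Continuous number of extrapolation fields of view.
#' @examples
#' n3e_from_effort(design_point(1, 27), effort = 1000, n3c = 17)
#' @export
n3e_from_effort <- function(dp, effort, n3c) {
  check_primal(dp)
  stopifnot_scalar(effort, "effort", 0, strict = TRUE)
  stopifnot_scalar(n3c, "n3c", 0, strict = TRUE)
  spent <- (dp$omega + dp$density) * n3c
  if (effort < spent)
    stop(sprintf(
      "calibration exhausts budget: %g calibration FOVs cost %.3f > effort %.3f",
      n3c, spent, effort), call. = FALSE)
  (effort - spent) / (dp$omega + dp$density / dp$u_hat)
}

# Shared root expression of the optimal-allocation algebra.
alloc_root <- function(dp) {
  sqrt((dp$omega + dp$density) * (dp$omega * dp$u_hat + dp$density))
}

#' Optimal allocation of fields of view for a fixed effort
#'
#' Minimising the FOVS error surface along the fixed-effort constraint gives
#' the stationary allocation
#' \deqn{N_{3C}^* = \frac{e_F}{\omega + \bar{Y}_{3x} + R}, \quad
#'       N_{3E}^* = \frac{e_F\,\hat{u}}{\omega\hat{u} + \bar{Y}_{3x} + R},
#'       \quad R = \sqrt{(\omega+\bar{Y}_{3x})(\omega\hat{u}+\bar{Y}_{3x})},}
#' and the budget-free optimal count ratio
#' \deqn{\delta^* = N_{3E}^*/N_{3C}^* =
#'   \hat{u}\sqrt{\frac{\omega+\bar{Y}_{3x}}{\omega\hat{u}+\bar{Y}_{3x}}},}
#' which equals 1 at `u = 1` and grows like `sqrt(u)`.  Field counts are
#' integers in practice: both are rounded to the nearest whole number (halves
#' away from zero) with a floor of 1.
#'
#' @inheritParams error_vs_effort_linear
#' @return An object of class `"fov_allocation"`: list with continuous
#'   `n3c_star`, `n3e_star`, rounded `n3c`, `n3e`, `delta_star` and the
#'   `effort` budget used.
#' @examples
#' optimal_allocation(design_point(10, 27), effort = 1000.3)  # (15, 119)
#' @export
optimal_allocation <- function(dp, effort) {
  check_primal(dp)
  stopifnot_scalar(effort, "effort", 0, strict = TRUE)
  r <- alloc_root(dp)
  n3c_star <- effort / (dp$omega + dp$density + r)
  n3e_star <- effort * dp$u_hat / (dp$omega * dp$u_hat + dp$density + r)
  if (n3c_star < 0.5 || n3e_star < 0.5) {
    e_min <- 0.5 * max(dp$omega + dp$density + r,
                       (dp$omega * dp$u_hat + dp$density + r) / dp$u_hat)
    stop(sprintf(
      "effort budget too small for any allocation; at least %.2f units needed",
      e_min), call. = FALSE)
  }
  structure(
    list(n3c_star = n3c_star, n3e_star = n3e_star,
         n3c = max(1, round_half_up(n3c_star)),
         n3e = max(1, round_half_up(n3e_star)),
         delta_star = n3e_star / n3c_star,
         effort = effort),
    class = "fov_allocation")
}

#' @export
print.fov_allocation <- function(x, ...) {
  cat(sprintf(
    "Optimal FOV allocation for effort %.1f: N3C* = %d, N3E* = %d (delta* = %.3f)\n",
    x$effort, x$n3c, x$n3e, x$delta_star))
  invisible(x)
}

#' Optimal extrapolation-to-calibration count ratio
#'
#' See [optimal_allocation()]; this is the budget-independent ratio alone.
#'
#' @inheritParams effort_coefficient
#' @return `delta*`, positive.
#' @examples
#' delta_star(design_point(1, 27))   # exactly 1
#' delta_star(design_point(30, 27))
#' @export
delta_star <- function(dp) {
  check_primal(dp)
  dp$u_hat * sqrt((dp$omega + dp$density) /
                    (dp$omega * dp$u_hat + dp$density))
}

#' FOVS error as a function of effort at the optimal allocation
#'
#' Substituting the optimal allocation into the error surface collapses the
#' two-dimensional problem to
#' \deqn{\sigma_F(e_F) = 100\sqrt{T +
#'   \frac{\omega(1+\hat{u}) + 2\bar{Y}_{3x} + 2R}{e_F\,\bar{Y}_{3x}}},}
#' with `R` as in [optimal_allocation()]; the same inverse-square-root law in
#' effort as the linear method.
#'
#' @inheritParams error_vs_effort_linear
#' @return Predicted total standard error in percent.
#' @examples
#' error_vs_effort_fovs(design_point(1, 27), effort = 1000)
#' @export
error_vs_effort_fovs <- function(dp, effort) {
  check_primal(dp)
  stopifnot_scalar(effort, "effort", 0, strict = TRUE)
  num <- dp$omega * (1 + dp$u_hat) + 2 * dp$density + 2 * alloc_root(dp)
  100 * sqrt(dp$dose_error + num / (effort * dp$density))
}

#' Error ratio of the two methods at equal effort
#'
#' \eqn{\sigma_L/\sigma_F} at a common effort budget; values above 1 mean
#' the FOVS method delivers the smaller error.  The ratio crosses 1 exactly
#' at the critical density [critical_density()], for any effort and any dose
#' error (those terms cancel on the dividing line).
#'
#' @inheritParams error_vs_effort_linear
#' @return The error ratio (ratio of standard errors, not of variances).
#' @examples
#' error_ratio(design_point(30, 27), effort = 1000)  # > 1: FOVS wins
#' @export
error_ratio <- function(dp, effort) {
  check_primal(dp)
  stopifnot_scalar(effort, "effort", 0, strict = TRUE)
  te <- dp$dose_error * effort
  y <- dp$density; u <- dp$u_hat; w <- dp$omega
  num <- w * (u + 1) + (2 + te + u) * y + y / u
  den <- w * (u + 1) + (2 + te) * y + 2 * alloc_root(dp)
  sqrt(num / den)
}

#' Critical common-specimen density for the method choice
#'
#' The density of common specimens per field of view at which the two
#' methods are equally efficient; above it the FOVS method gives the smaller
#' error for the same effort.  Closed form of the dividing-line equation
#' \eqn{(u^2-1)^2 Y^2 - 4\omega u^2(1+u)Y - 4\omega^2 u^3 = 0}:
#' \deqn{\bar{Y}_{3x}^* = \frac{2\omega\left(\hat{u}^2 +
#'   \sqrt{\hat{u}^3\,(1 + \hat{u}[\hat{u}-1])}\right)}
#'   {(\hat{u}+1)(\hat{u}-1)^2},}
#' strictly decreasing in `u` for `u > 1` and infinite at `u = 1`, where the
#' linear method is always (marginally) superior.
#'
#' @param u_hat Common-to-rare ratio, `>= 1` (apply [reversed_role()] logic
#'   for the opposite orientation).
#' @param omega Transition effort factor; non-negative.
#' @return The critical density (`Inf` at `u_hat = 1`).
#' @examples
#' critical_density(2, 2)    # 11.87
#' critical_density(60, 2)   # 0.5888
#' critical_density(1, 2)    # Inf
#' @export
critical_density <- function(u_hat, omega) {
  stopifnot_scalar(u_hat, "u_hat", 0, strict = TRUE)
  stopifnot_scalar(omega, "omega", 0)
  if (u_hat < 1)
    stop("u_hat < 1: compute the critical density of the reversed-role ",
         "orientation (see reversed_role())", call. = FALSE)
  if (u_hat == 1) {
    message("u_hat = 1: linear method always superior (critical density infinite)")
    return(Inf)
  }
  u <- u_hat
  2 * omega * (u^2 + sqrt(u^3 * (1 + u * (u - 1)))) /
    ((u + 1) * (u - 1)^2)
}

#' Method-determination test
#'
#' Compares the observed common-specimen density with the critical density:
#' recommend the FOVS method when `density > critical`, the linear method
#' when below, and the linear method (flagged `"equivalent"`) on a tie,
#' since the linear method needs no further assumptions.
#'
#' @inheritParams effort_coefficient
#' @param effort Effort budget at which the error ratio is reported
#'   (default 1000, a routine count of several hundred specimens); the
#'   recommendation itself does not depend on it.
#' @param tol Relative tolerance for calling a tie.
#' @return An object of class `"method_choice"`: list with
#'   `critical_density`, `recommended` (`"linear"` or `"fovs"`), `tie`
#'   (logical) and `error_ratio` at `effort`.
#' @examples
#' choose_method(design_point(2, 27))    # fovs
#' choose_method(design_point(1.2, 27))  # linear
#' @export
choose_method <- function(dp, effort = 1000, tol = 1e-8) {
  check_primal(dp)
  crit <- if (dp$u_hat == 1) Inf else critical_density(dp$u_hat, dp$omega)
  tie <- is.finite(crit) &&
    abs(dp$density - crit) <= tol * max(dp$density, crit)
  recommended <- if (!tie && dp$density > crit) "fovs" else "linear"
  structure(
    list(critical_density = crit, recommended = recommended, tie = tie,
         error_ratio = error_ratio(dp, effort), effort = effort),
    class = "method_choice")
}

#' @export
print.method_choice <- function(x, ...) {
  cat(sprintf("Critical density: %s per FOV\n",
              format(x$critical_density, digits = 4)))
  cat(sprintf("Recommended method: %s%s (error ratio sigma_L/sigma_F = %.3f at effort %.0f)\n",
              x$recommended, if (x$tie) " (methods equivalent)" else "",
              x$error_ratio, x$effort))
  invisible(x)
}

check_reachable <- function(dp, sigma_bar) {
  stopifnot_scalar(sigma_bar, "sigma_bar", 0, strict = TRUE)
  if (pct_to_var(sigma_bar) <= dp$dose_error)
    stop(sprintf(
      "target error unattainable: limited by marker-dose uncertainty (floor %.3f %%)",
      100 * sqrt(dp$dose_error)), call. = FALSE)
  invisible(sigma_bar)
}

#' Linear-method effort for a target precision
#'
#' Exact inverse of [error_vs_effort_linear()]:
#' \deqn{e_L(\bar\sigma) = \frac{\omega(1+\hat{u}) + \bar{Y}_{3x}(2+\hat{u})
#'   + \bar{Y}_{3x}/\hat{u}}{\bar{Y}_{3x}\,([\bar\sigma/100]^2 - T)}.}
#' Unattainable targets (at or below the dose-error floor) raise an error.
#'
#' @inheritParams effort_coefficient
#' @param sigma_bar Desired total standard error in percent.
#' @return Required effort in specimen-count time units.
#' @examples
#' effort_for_error_linear(design_point(3, 10), sigma_bar = 10)
#' @export
effort_for_error_linear <- function(dp, sigma_bar) {
  check_primal(dp)
  check_reachable(dp, sigma_bar)
  y <- dp$density; u <- dp$u_hat; w <- dp$omega
  (w * (1 + u) + y * (2 + u) + y / u) /
    (y * (pct_to_var(sigma_bar) - dp$dose_error))
}

#' Optimal field-of-view counts for a target precision
#'
#' Solves the optimally-allocated FOVS error for the number of fields of
#' view needed to reach `sigma_bar`:
#' \deqn{N_{3C}^*(\bar\sigma) = \frac{\sqrt{\bar{Y}+\omega} +
#'   \sqrt{\bar{Y}+\hat{u}\omega}}{\bar{Y}\sqrt{\bar{Y}+\omega}\,
#'   ([\bar\sigma/100]^2 - T)}}
#' and the matching `N3E*`; their ratio is exactly [delta_star()].
#'
#' @inheritParams effort_for_error_linear
#' @return A `"fov_allocation"` (as for [optimal_allocation()], with
#'   `effort` the implied budget from [effort_for_error_fovs()]).
#' @examples
#' allocation_for_error(design_point(30, 27), sigma_bar = 6.9)
#' @export
allocation_for_error <- function(dp, sigma_bar) {
  check_primal(dp)
  check_reachable(dp, sigma_bar)
  y <- dp$density; u <- dp$u_hat; w <- dp$omega
  gap <- pct_to_var(sigma_bar) - dp$dose_error
  s_c <- sqrt(y + w); s_e <- sqrt(y + u * w)
  n3c_star <- (s_c + s_e) / (y * s_c * gap)
  n3e_star <- u * (s_c + s_e) / (y * s_e * gap)
  structure(
    list(n3c_star = n3c_star, n3e_star = n3e_star,
         n3c = max(1, round_half_up(n3c_star)),
         n3e = max(1, round_half_up(n3e_star)),
         delta_star = n3e_star / n3c_star,
         effort = effort_for_error_fovs(dp, sigma_bar)),
    class = "fov_allocation")
}

#' FOVS effort for a target precision
#'
#' Exact inverse of [error_vs_effort_fovs()]:
#' \deqn{e_F(\bar\sigma) = \frac{2\bar{Y}_{3x} + \omega(1+\hat{u}) +
#'   2\sqrt{(\bar{Y}_{3x}+\omega)(\bar{Y}_{3x}+\hat{u}\omega)}}
#'   {\bar{Y}_{3x}\,([\bar\sigma/100]^2 - T)}.}
#'
#' @inheritParams effort_for_error_linear
#' @return Required effort in specimen-count time units.
#' @examples
#' effort_for_error_fovs(design_point(20, 10), sigma_bar = 10)
#' @export
effort_for_error_fovs <- function(dp, sigma_bar) {
  check_primal(dp)
  check_reachable(dp, sigma_bar)
  y <- dp$density; u <- dp$u_hat; w <- dp$omega
  (2 * y + w * (1 + u) + 2 * alloc_root(dp)) /
    (y * (pct_to_var(sigma_bar) - dp$dose_error))
}

#' Effort difference between the methods at a target precision
#'
#' `effort_for_error_linear(dp, sigma_bar) - effort_for_error_fovs(dp,
#' sigma_bar)`: positive values quantify the effort the FOVS method saves,
#' negative values favour the linear method.  The sign agrees with
#' [choose_method()] for all valid inputs and the difference vanishes at the
#' critical density.
#'
#' @inheritParams effort_for_error_linear
#' @return Effort difference (linear minus FOVS), in effort units.
#' @examples
#' effort_difference(design_point(10, 10), sigma_bar = 10)  # > 0
#' @export
effort_difference <- function(dp, sigma_bar) {
  effort_for_error_linear(dp, sigma_bar) - effort_for_error_fovs(dp, sigma_bar)
}
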