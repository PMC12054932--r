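#' Simulation configuration
#'
#' Defines one virtual-study-area scenario: known numbers of targets and
#' markers scattered uniformly at random on a unit square, a
#' `grid_side x grid_side` grid of non-overlapping fields of view (1089 by
#' default), a linear-method window anchored in a strip of
#' `window_height_fovs` FOV rows along the bottom edge, and the counting
#' parameters shared by both methods.  The true concentration is
#' `n_targets` per unit sample, and the true common-to-rare ratio is
#' `n_targets / n_markers`.
#'
#' @param n_targets True number of target specimens (default 30000).
#' @param n_markers True number of marker specimens; must not exceed
#'   `n_targets` (markers-common scenarios are studied by relabelling).
#' @param x_stop Linear-method stopping count of targets.  If `NULL`, it is
#'   derived from `effort_budget` via the expected effort per specimen.
#' @param effort_budget Optional effort budget; if `x_stop` is given (the
#'   usual case) the budget defaults to the expected linear effort
#'   `A * x_stop`.
#' @param omega Transition effort factor (default 2).
#' @param dose_sd SD of markers per dose; markers are always placed in exact
#'   number (the spike is treated as a single dose of `n_markers`), so this
#'   only feeds the dose-error term of the *estimated* errors. Default 0.
#' @param iterations Number of Monte Carlo replicates.
#' @param seed Integer RNG seed.
#' @param grid_side Number of FOV rows/columns (default 33).
#' @param window_height_fovs Height of the linear window strip in FOV rows
#'   (default 1).  Choose it so the strip comfortably holds `x_stop`
#'   targets: with the default grid a row holds about `n_targets / 33`
#'   targets on average, so stopping counts near that number need 2 rows.
#' @param design_density Density of common specimens per FOV used in the
#'   *planning* formulas (effort budget and optimal allocation).  Defaults
#'   to the exact `n_targets / grid_side^2`; set it to a rounded
#'   calibration-style value to mirror designs planned from an observed
#'   per-FOV mean.
#' @return An object of class `"sim_config"`.
#' @examples
#' sim_config(n_markers = 1000, x_stop = 903, iterations = 1000, seed = 1)
#' @export
sim_config <- function(n_targets = 30000, n_markers,
                       x_stop = NULL, effort_budget = NULL,
                       omega = 2, dose_sd = 0, iterations = 10000,
                       seed = 1, grid_side = 33, window_height_fovs = 1,
                       design_density = NULL) {
  stopifnot_scalar(n_targets, "n_targets", 1)
  stopifnot_scalar(n_markers, "n_markers", 1)
  stopifnot_scalar(omega, "omega", 0)
  stopifnot_scalar(dose_sd, "dose_sd", 0)
  stopifnot_scalar(iterations, "iterations", 1)
  stopifnot_scalar(grid_side, "grid_side", 1)
  stopifnot_scalar(window_height_fovs, "window_height_fovs", 1)
  if (window_height_fovs > grid_side)
    stop("`window_height_fovs` cannot exceed `grid_side`", call. = FALSE)
  if (n_markers > n_targets)
    stop("markers more common than targets: swap the labels ",
         "(the design module's reversed_role() documents the symmetry)",
         call. = FALSE)
  density <- n_targets / grid_side^2
  if (is.null(design_density)) design_density <- density
  stopifnot_scalar(design_density, "design_density", 0, strict = TRUE)
  u_true <- n_targets / n_markers
  a_coef <- omega / design_density + 1 + 1 / u_true
  if (is.null(x_stop)) {
    if (is.null(effort_budget))
      stop("supply `x_stop` or `effort_budget`", call. = FALSE)
    x_stop <- max(1, round_half_up(effort_budget / a_coef))
  }
  stopifnot_scalar(x_stop, "x_stop", 1)
  if (is.null(effort_budget)) effort_budget <- a_coef * x_stop
  structure(
    list(n_targets = as.integer(n_targets),
         n_markers = as.integer(n_markers),
         x_stop = as.integer(x_stop),
         effort_budget = effort_budget,
         omega = omega, dose_sd = dose_sd,
         iterations = as.integer(iterations),
         seed = as.integer(seed),
         grid_side = as.integer(grid_side),
         window_height_fovs = as.integer(window_height_fovs),
         u_true = u_true, density = density,
         design_density = design_density,
         dose_error = (dose_sd / n_markers)^2),
    class = "sim_config")
}

#' Generate one virtual study area
#'
#' Scatters exactly `n_targets` target and `n_markers` marker coordinates
#' i.i.d. uniformly on the unit square.  Deterministic given
#' `(cfg$seed, replicate)`.
#'
#' @param cfg A [sim_config()].
#' @param replicate Replicate index (>= 1); folded into the seed.
#' @return An object of class `"study_area"`: list with `target_coords` and
#'   `marker_coords` (two-column matrices) and the grid side.
#' @examples
#' area <- generate_study_area(sim_config(n_markers = 1000, x_stop = 903))
#' nrow(area$target_coords)
#' @export
generate_study_area <- function(cfg, replicate = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed((cfg$seed + 7919L * as.integer(replicate)) %% 2147483647L)
  structure(
    list(target_coords = cbind(x = stats::runif(cfg$n_targets),
                               y = stats::runif(cfg$n_targets)),
         marker_coords = cbind(x = stats::runif(cfg$n_markers),
                               y = stats::runif(cfg$n_markers)),
         grid_side = cfg$grid_side),
    class = "study_area")
}

# Half-open cell index (1-based, row-major from the bottom-left corner):
# each specimen belongs to exactly one cell, which implements the "count
# half of the margin specimens" rule without double counting.
cell_index <- function(coords, grid_side) {
  cx <- pmin(floor(coords[, 1] * grid_side), grid_side - 1)
  cy <- pmin(floor(coords[, 2] * grid_side), grid_side - 1)
  as.integer(cy * grid_side + cx + 1)
}

#' Linear-method count on a study area
#'
#' Marks out a strip of `cfg$window_height_fovs` FOV rows along the bottom
#' edge and sweeps it from the left until `x_stop` targets are enclosed; the
#' window length is the x-coordinate of the stopping target and every marker
#' in the strip at or left of it is counted.  Returns the concentration,
#' estimated error and effort of that single linear count (marker total
#' known exactly; sample size 1 unit).
#'
#' @param area A [generate_study_area()] result.
#' @param x_stop Stopping target count; the strip must contain at least this
#'   many targets.
#' @param cfg The [sim_config()] the area was drawn from.
#' @return A list (`"replicate_result"`): `method`, `c_hat`,
#'   `sigma_hat_pct`, `effort`, `counts` (x, n), `window_length`.
#' @export
linear_window_count <- function(area, x_stop, cfg) {
  stopifnot(inherits(area, "study_area"), inherits(cfg, "sim_config"))
  strip_h <- cfg$window_height_fovs / cfg$grid_side
  in_strip_t <- area$target_coords[, 2] < strip_h
  if (sum(in_strip_t) < x_stop)
    stop(sprintf("strip contains only %d targets (< x_stop = %d)",
                 sum(in_strip_t), x_stop), call. = FALSE)
  tx <- sort(area$target_coords[in_strip_t, 1])
  cut <- tx[x_stop]
  in_strip_m <- area$marker_coords[, 2] < strip_h
  n <- sum(area$marker_coords[in_strip_m, 1] <= cut)
  if (n < 1)
    return(structure(list(method = "linear", ok = FALSE,
                          reason = "no markers in window"),
                     class = "replicate_result"))
  tally <- linear_tally(x_stop, n)
  spike <- marker_spike(1, cfg$n_markers, cfg$dose_sd)
  structure(
    list(method = "linear", ok = TRUE,
         c_hat = concentration_linear(tally, spike),
         sigma_hat_pct = error_linear(tally, spike),
         effort = effort_linear(tally, cfg$omega, cfg$density),
         counts = c(x = x_stop, n = n),
         window_length = cut),
    class = "replicate_result")
}

#' FOVS count on a study area
#'
#' Draws `n3c + n3e` distinct cells uniformly without replacement from the
#' FOV grid (calibration and extrapolation sets disjoint), computes the
#' calibration statistics from the target counts of the first `n3c` cells
#' and the rare (marker) count from the remaining `n3e`, and returns the
#' FOVS estimate with the finite-population correction applied to the
#' calibration error term.
#'
#' @inheritParams linear_window_count
#' @param n3c,n3e Calibration and extrapolation cell counts.
#' @param cells Optional integer vector of `n3c + n3e` distinct cell indices
#'   (1-based, row-major); drawn at random when `NULL`.  Supplying it makes
#'   the computation fully deterministic.
#' @return A `"replicate_result"` as for [linear_window_count()], with
#'   `counts` holding (x = calibration total, n = rare count, N3C, N3E);
#'   `ok = FALSE` with a reason when the extrapolation cells hold no rare
#'   specimens (the estimator is undefined there).
#' @export
fov_replicate <- function(area, n3c, n3e, cfg, cells = NULL) {
  stopifnot(inherits(area, "study_area"), inherits(cfg, "sim_config"))
  n_cells <- cfg$grid_side^2
  if (n3c + n3e > n_cells)
    stop("n3c + n3e exceeds the number of grid cells", call. = FALSE)
  if (is.null(cells)) cells <- sample.int(n_cells, n3c + n3e)
  if (anyDuplicated(cells) || length(cells) != n3c + n3e)
    stop("`cells` must hold n3c + n3e distinct cell indices", call. = FALSE)
  tab_t <- tabulate(cell_index(area$target_coords, cfg$grid_side), n_cells)
  tab_m <- tabulate(cell_index(area$marker_coords, cfg$grid_side), n_cells)
  calib_counts <- tab_t[cells[seq_len(n3c)]]
  rare <- sum(tab_m[cells[n3c + seq_len(n3e)]])
  if (rare < 1)
    return(structure(list(method = "fovs", ok = FALSE,
                          reason = "no rare specimens in extrapolation cells"),
                     class = "replicate_result"))
  if (all(calib_counts == 0))
    return(structure(list(method = "fovs", ok = FALSE,
                          reason = "no common specimens in calibration cells"),
                     class = "replicate_result"))
  calib <- calibration_stats(calib_counts)
  extrap <- fov_extrapolation(n3e, rare)
  spike <- marker_spike(1, cfg$n_markers, cfg$dose_sd)
  fpc <- fpc_factor(n_cells, n3c)
  structure(
    list(method = "fovs", ok = TRUE,
         c_hat = concentration_fovs(calib, extrap, spike),
         sigma_hat_pct = error_fovs(calib, extrap, spike, fpc = fpc),
         effort = effort_fovs(calib, extrap, cfg$omega),
         counts = c(x = sum(calib_counts), n = rare, N3C = n3c, N3E = n3e)),
    class = "replicate_result")
}

#' Finite-population correction factor
#'
#' The standard survey-sampling shrinkage of a sample-mean standard error
#' when a non-negligible fraction of a finite population of units is
#' sampled without replacement:
#' \deqn{\mathrm{FPC} = \sqrt{\frac{N - n}{N - 1}},}
#' 1 for a single sampled unit and 0 for a census.
#'
#' @param population_units Total number of units (e.g. grid cells); `>= 1`.
#' @param sampled_units Number sampled; between 1 and `population_units`.
#' @return The correction factor in `[0, 1]`.
#' @examples
#' fpc_factor(1089, 17)
#' @export
fpc_factor <- function(population_units, sampled_units) {
  stopifnot_scalar(population_units, "population_units", 1)
  stopifnot_scalar(sampled_units, "sampled_units", 1)
  if (sampled_units > population_units)
    stop("cannot sample more units than the population holds", call. = FALSE)
  if (population_units == 1) return(0)
  sqrt((population_units - sampled_units) / (population_units - 1))
}

#' Run a full Monte Carlo comparison experiment
#'
#' For each replicate a fresh study area is generated; the linear method is
#' applied at `cfg$x_stop`, and the FOVS method at the optimal allocation
#' [optimal_allocation()] computed once from the *expected* linear effort
#' `A * x_stop` (so both methods spend near-identical effort).  Replicates
#' where an estimator is undefined (no rare specimens in the extrapolation
#' cells, or no markers in the window) are excluded from the summaries and
#' reported as a rate.  The heavy per-replicate counting runs in compiled
#' code; results are reproducible under `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param allocation Optional `"fov_allocation"` overriding the computed
#'   one.
#' @return An object of class `"sim_summary"`: list with the `allocation`,
#'   the effort-matching budget, and per-method summaries (`linear`,
#'   `fovs`), each holding `mean_c`, `mean_sigma_pct`,
#'   `empirical_sigma_pct` (100 x SD of the estimates / true
#'   concentration), `rms_error_pct` (100 x RMS relative deviation from
#'   truth), `mean_effort`, `n_used` and `n_excluded`.
#' @examples
#' \donttest{
#' run_experiment(sim_config(n_markers = 30000, x_stop = 482,
#'                           iterations = 2000, seed = 42))
#' }
#' @export
run_experiment <- function(cfg, allocation = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  dp <- design_point(cfg$u_true, cfg$design_density, cfg$omega,
                     cfg$dose_error)
  if (is.null(allocation))
    allocation <- optimal_allocation(dp, cfg$effort_budget)
  n3c <- allocation$n3c
  n3e <- allocation$n3e

  set.seed(cfg$seed)
  raw <- cpp_sim_replicates(cfg$iterations, cfg$n_targets, cfg$n_markers,
                            cfg$grid_side, cfg$window_height_fovs,
                            cfg$x_stop, n3c, n3e)
  marker_total <- as.numeric(cfg$n_markers)
  c_true <- as.numeric(cfg$n_targets)
  T <- cfg$dose_error

  # linear summaries (vectorised over replicates)
  n_win <- raw[, 1]
  ok_l <- !is.na(n_win) & n_win >= 1
  x <- as.numeric(cfg$x_stop)
  c_l <- x * marker_total / n_win[ok_l]
  sig_l <- 100 * sqrt(T + 1 / x + 1 / n_win[ok_l])
  eff_l <- cfg$omega * x / cfg$density + x + n_win[ok_l]

  # FOVS summaries
  ybar3 <- raw[, 2 + 1]  # col 3: calibration mean
  s3 <- raw[, 4]
  calib_sum <- raw[, 5]
  rare <- raw[, 6]
  ok_f <- rare >= 1 & ybar3 > 0
  s3p <- s3[ok_f] / (c4_factor(n3c) * ybar3[ok_f])
  fpc <- fpc_factor(cfg$grid_side^2, n3c)
  c_f <- ybar3[ok_f] * n3e * marker_total / rare[ok_f]
  sig_f <- 100 * sqrt(T + (fpc * s3p)^2 / n3c + 1 / rare[ok_f])
  eff_f <- cfg$omega * (n3c + n3e) + calib_sum[ok_f] + rare[ok_f]

  summarise <- function(c_hat, sig, eff, n_total) {
    list(mean_c = mean(c_hat),
         mean_sigma_pct = mean(sig),
         empirical_sigma_pct = 100 * stats::sd(c_hat) / c_true,
         rms_error_pct = 100 * sqrt(mean((c_hat / c_true - 1)^2)),
         mean_effort = mean(eff),
         n_used = length(c_hat),
         n_excluded = n_total - length(c_hat))
  }
  structure(
    list(config = cfg, allocation = allocation,
         linear = summarise(c_l, sig_l, eff_l, cfg$iterations),
         fovs = summarise(c_f, sig_f, eff_f, cfg$iterations),
         c_true = c_true),
    class = "sim_summary")
}

#' @export
print.sim_summary <- function(x, ...) {
  cat(sprintf(
    "Simulated comparison: %d targets, %d markers (u = %.3g), %d iterations\n",
    x$config$n_targets, x$config$n_markers, x$config$u_true,
    x$config$iterations))
  cat(sprintf("FOVS allocation: N3C = %d, N3E = %d (budget %.1f)\n",
              x$allocation$n3c, x$allocation$n3e, x$config$effort_budget))
  fmt <- function(m, s) sprintf(
    "  %-6s mean c = %.0f | mean sigma = %.3f%% | empirical sigma = %.3f%% | effort = %.0f | excluded = %d\n",
    m, s$mean_c, s$mean_sigma_pct, s$empirical_sigma_pct, s$mean_effort,
    s$n_excluded)
  cat(fmt("linear", x$linear))
  cat(fmt("fovs", x$fovs))
  invisible(x)
}
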