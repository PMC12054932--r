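# Shared builders for small deterministic fixtures.

unit_spike <- function(total = 1000, sd = 0) marker_spike(1, total, sd)

# A study area with hand-placed coordinates, for deterministic counting
# tests.  `targets` / `markers` are two-column matrices in [0, 1)^2.
manual_area <- function(targets, markers, grid_side) {
  structure(list(target_coords = targets, marker_coords = markers,
                 grid_side = grid_side),
            class = "study_area")
}

# The eleven simulated-study scenarios: common-to-rare ratio, linear
# stopping count, and the optimal FOV allocation each implies at a per-FOV
# density of 27 and omega = 2.
study_scenarios <- function() {
  data.frame(
    u = c(1, 1.2, 1.5, 2, 3, 6, 10, 15, 20, 30, 60),
    x_stop = c(482, 524, 574, 635, 711, 806, 852, 877, 890, 903, 917),
    n3c = c(17, 17, 17, 17, 17, 16, 15, 14, 14, 13, 11),
    n3e = c(17, 20, 25, 33, 47, 83, 119, 154, 180, 219, 283))
}

# Chi-square goodness-of-fit of integer counts against a Poisson law with
# the given (estimated) mean; tail bins pooled to expected counts >= 5.
# Returns the p-value; df loses one for the estimated mean.
poisson_gof_pvalue <- function(counts, lambda = mean(counts)) {
  kmax <- max(counts)
  obs <- tabulate(counts + 1L, kmax + 1L)
  expd <- length(counts) * stats::dpois(0:kmax, lambda)
  expd[kmax + 1L] <- expd[kmax + 1L] +
    length(counts) * stats::ppois(kmax, lambda, lower.tail = FALSE)
  # pool adjacent bins until every expected count is >= 5
  o <- numeric(0); e <- numeric(0)
  acc_o <- 0; acc_e <- 0
  for (i in seq_along(obs)) {
    acc_o <- acc_o + obs[i]; acc_e <- acc_e + expd[i]
    if (acc_e >= 5) {
      o <- c(o, acc_o); e <- c(e, acc_e)
      acc_o <- 0; acc_e <- 0
    }
  }
  if (acc_e > 0) {
    o[length(o)] <- o[length(o)] + acc_o
    e[length(e)] <- e[length(e)] + acc_e
  }
  stat <- sum((o - e)^2 / e)
  stats::pchisq(stat, df = length(o) - 2, lower.tail = FALSE)
}
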