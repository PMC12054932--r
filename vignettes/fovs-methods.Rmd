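---
title: "Absolute abundances from exotic markers: models, design calculus and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute abundances from exotic markers: models, design calculus and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fovs)
```

## The estimation problem

A sample of known total size $\bar V$ (mass, area or volume) contains an
unknown number of *target* specimens — pollen, spores, phytoclasts, cells,
any countable particle.  Before processing, $N_1$ doses of *exotic markers*
(classically, tablets of modern *Lycopodium clavatum* spores) with a known
mean of $\bar Y_1$ markers per dose are mixed in.  If markers and targets
mix homogeneously, the ratio of targets to markers in any subsample
estimates their ratio in the whole sample, and the target concentration
follows from the known marker total.  The package implements two ways of
collecting that ratio and everything needed to choose between them and to
plan the counting effort.

### The linear method

Targets ($x$) and markers ($n$) are identified jointly and sequentially in
one contiguous window until a pre-set count is reached.  The concentration
estimator is

$$c_L = \frac{x\,N_1\bar Y_1}{n\,\bar V},$$

and, treating both counts as Poisson (uniform random scatter) and the dose
total as normal with proportional SD $s_{1P} = s_1/\bar Y_1$,

$$\sigma_L = 100\sqrt{T + \frac1x + \frac1n}\ (\%),
\qquad T = \frac{s_{1P}^2}{N_1}.$$

$T$ is a floor: $\sigma$ can never fall below $100\sqrt T$ however long one
counts.  Even the pre-determined count contributes a $1/\cdot$ term,
because fixing it randomises the window extent instead.

### The field-of-view subsampling (FOVS) method

Counting every specimen is wasteful when one type vastly outnumbers the
other.  The FOVS method splits the work in two stages over equal-area
fields of view (FOVs):

1. **Calibration**: count the *common* type exhaustively in $N_{3C}$ FOVs,
   giving the per-FOV mean $\bar Y_3$ and Bessel-corrected SD $s_3$.
2. **Extrapolation**: scan $N_{3E}$ fresh FOVs counting only the *rare*
   type (total $n$).

The implied common count over the extrapolation area is
$\hat x = \bar Y_3 N_{3E}$, and $\hat x$ replaces $x$ in the concentration
formula.  Its error combines a central-limit term for the calibration mean
with the Poisson term of the rare count:

$$\sigma_F = 100\sqrt{T + \frac{s_{3P}^2}{N_{3C}} + \frac1n},
\qquad s_{3P} = \frac{s_3}{c_4(N_{3C})\,\bar Y_3}.$$

The $c_4(n) = \sqrt{2/(n-1)}\,\Gamma(n/2)/\Gamma((n-1)/2)$ factor removes
the small-sample downward bias of $s_3$ under a normal model; it matters at
calibration sizes of 10–20 FOVs ($c_4(17) = 0.985$) and is applied inside
$s_{3P}$ only — dose statistics are taken as the producer reports them.
At the rare-count densities this method is meant for (roughly 0.2–5 per
FOV) the Poisson approximation for $n$ is excellent; the test suite checks
it by chi-square goodness of fit on simulated scatters.

### Effort

Effort is a time proxy: one unit per specimen identified plus $\omega$
units per FOV transition, where $\omega$ is the researcher-specific ratio
of transition time to single-specimen count time (default 2, measured at
the microscope for total-organic-microfossil counting):

$$e_L = \frac{\omega x}{\bar Y_{3x}} + x + n, \qquad
  e_F = \omega N_{3C} + x + \omega N_{3E} + n.$$

Both accept an optional *effort asymmetry factor* multiplying the target
identifications, for work at high taxonomic resolution where targets take
longer to verify than markers; the default of 1 assumes equal
identification time.

## The design calculus

Writing $\hat u$ for the common-to-rare ratio and $\bar Y_{3x}$ for the
common density per FOV, the expected linear effort is $e_L = A x$ with
$A = \omega/\bar Y_{3x} + 1 + 1/\hat u$, giving the error-versus-effort
curve $\sigma_L(e_L) = 100\sqrt{T + (1+\hat u)A/e_L}$.  For the FOVS
method, approximating the calibration term by its Poisson value and
minimising the two-dimensional error surface along a fixed-effort
constraint yields closed forms for the optimal allocation
$(N_{3C}^*, N_{3E}^*)$, the budget-free count ratio

$$\delta^* = \hat u\sqrt{\frac{\omega + \bar Y_{3x}}
                              {\omega\hat u + \bar Y_{3x}}},$$

($\delta^* = 1$ at $\hat u = 1$, growing like $\sqrt{\hat u}$), and the
collapsed curve $\sigma_F(e_F)$.  Both methods share the inverse
square-root law — quadrupling effort halves the error — so their ratio at
equal effort is effort-free on the dividing line, which has the closed-form
root

$$\bar Y_{3x}^* = \frac{2\omega\big(\hat u^2 +
  \sqrt{\hat u^3(1+\hat u[\hat u - 1])}\big)}
  {(\hat u + 1)(\hat u - 1)^2}.$$

`choose_method()` recommends FOVS exactly when the observed density
exceeds $\bar Y_{3x}^*$.  At $\hat u = 1$ the critical density is infinite:
the linear method is always (marginally) the better choice when targets and
markers are balanced.  Every planning function has an exact inverse for a
target error $\bar\sigma$ (`effort_for_error_*`, `allocation_for_error`),
with an informative error when $\bar\sigma$ lies at or below the dose floor
$100\sqrt T$.

Numerical choices made here, where the design was open:

* **Rounding** of optimal FOV counts is to the nearest integer, halves away
  from zero, floored at one.  This reproduces all eleven published
  simulation allocations, and the test suite verifies by exhaustive integer
  search that each rounded pair minimises the error among all pairs costing
  no more than itself.
* **Ties** at the critical density resolve to the linear method (it needs
  no distributional assumptions about per-FOV representativeness) and are
  flagged as equivalent.
* **Orientation**: the closed forms assume the calibration subject is the
  common type ($\hat u \ge 1$).  When markers outnumber targets,
  `reversed_role()` swaps the point ($\hat u' = 1/\hat u$, density mapped
  to the other type) and every formula applies verbatim; planning functions
  refuse $\hat u < 1$ rather than silently extrapolating.
* **Confidence intervals** are a normal approximation
  $c\,(1 \pm z\,\sigma/100)$, truncated at zero and labelled as such; the
  parametric intervals of the classical palynological literature are not
  reproduced here.
* Zero marker counts raise an error (the estimator is unbounded) rather
  than returning infinity; zero target counts return concentration 0 with
  an advisory.

## The Monte Carlo simulator

`sim_config()` / `run_experiment()` rebuild the validation study: each
replicate scatters exactly $\bar{\bar x}$ targets (default 30,000) and
$\bar{\bar n}$ markers i.i.d. uniformly on a unit square carrying a
$33 \times 33$ grid of non-overlapping FOVs.  Cells are half-open, so each
specimen belongs to exactly one FOV — the practical rule of counting only
half the margin specimens, without double counting.  The linear window is a
strip of whole FOV rows along the bottom edge, swept left to right until
the stopping count is enclosed; the FOVS replicate draws disjoint
calibration and extrapolation cell sets uniformly without replacement.
The marker total is specified exactly (a single exact dose), so $T = 0$
unless a dose SD is supplied — which then feeds the error *estimates* only.

Scenario choices, fixed once:

* **Planning density 27 per FOV.**  The published scenario allocations were
  planned from a per-FOV density of 27 (the value the study conditions
  state), slightly below the exact grid density $30000/1089 = 27.55$;
  paper-matching runs therefore pass `design_density = 27`.  The scatter
  itself always uses the exact counts.
* **Strip height 2 FOV rows** for stopping counts near 900: one row holds
  only ~909 targets on average and would exhaust mid-window in ~40% of
  replicates.  The window estimator is a within-window ratio, so strip
  height does not affect its distribution beyond availability.
* **Effort matching** uses the *expected* linear effort $A\,x_{stop}$ to set
  the FOVS budget, computed once per scenario — this reproduces every
  published allocation pair, unlike per-replicate matching.
* **Finite-population correction** $\sqrt{(N-n)/(N-1)}$ multiplies the
  calibration standard-error term only (the sampled cell fraction there is
  1–2%; the correction is isolated in `fpc_factor()`).
* Replicates whose extrapolation cells contain no rare specimen (where the
  estimator is undefined) are excluded and reported as a rate.
* The "exact" error of a method is operationalised as
  $100\times$ RMS relative deviation of the estimates from the known truth
  (`rms_error_pct`), alongside the relative SD (`empirical_sigma_pct`).

The per-replicate scatter-and-count loop is compiled (Rcpp) and draws from
R's RNG stream, so whole experiments are bit-reproducible from
`cfg$seed`; $10^5$ replicates of a scenario run in under a minute on one
core.  The shipped tests run four scenarios (ratios 1, 3, 10, 30) at
$10^5$ replicates each — the package's validation scale; the original
study used $10^6$, which `iterations` accepts unchanged.

### What the simulation shows — and a bias it exposes

Under these idealised conditions the FOVS error *estimates* track the
empirical scatter of the estimates to within a few percent at every tested
ratio, while the linear error estimate grows progressively too optimistic
as the ratio rises — the practical argument for the two-stage design.  The
efficiency crossover matches the closed-form prediction: at density ~27
the linear method wins only at $\hat u = 1$.

Both estimators, however, are *ratio* estimators: they divide by a random
count $n$, so their expectation exceeds the truth by approximately
$c\cdot\mathrm{CV}(n)^2$ — about $(1-f)/n$ for the FOVS rare count
(sampling fraction $f$) and $(1+\hat u)/x_{stop}$ for the linear window
(window-extent and thinning terms).  That is 0.2–3% across the study
grid: negligible against single-sample errors of 6–20%, but many Monte
Carlo standard errors at $10^5$ replicates.  The test suite therefore
carries one deliberately strict check (mean within 3 MC SE of truth) that
*fails* under these conditions, documenting the effect, alongside a
passing check that the measured bias matches the first-order
ratio-estimator prediction.  No bias correction is applied: the estimator
under study is the published one.

### What the generator does not emulate

Uniform random scatter means per-FOV counts are Poisson; real slides show
spatial heterogeneity (clumping, edge effects, density gradients), which
inflates $s_3$ and with it the true FOVS error.  Passing simulation checks
therefore validate the estimators and the design calculus under the
homogeneity assumption they are derived from — not robustness to
heterogeneous preparations, which both the error model (through $s_{3P}$)
and the method-choice test handle only to first order.  Clustered point
processes are deliberately out of scope.

## Batch interface

Delimited text is the interchange format: one-row-per-sample linear
tables, and long-format calibration tables paired with per-sample
extrapolation tables for FOVS counts (see `read_linear_counts()`,
`read_fovs_counts()`).  `estimate_batch()` isolates per-sample failures,
reports across-sample means (concentration, error, effort),
`write_results()` attaches a manifest (version, seed, input digests), and
`generate_fixtures()` emits simulator-derived tables with a JSON truth
sidecar for end-to-end testing.  Percentages are always on the 0–100
scale.  A thin command-line front end lives at
`inst/scripts/fovcount.R`.
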