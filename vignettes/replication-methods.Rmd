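---
title: "Methods: pooling PPI effects under small-study bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooling PPI effects under small-study bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppimeta)
```

## The data and the estimand

The package is built around five per-outcome effect tables
(`ppi_datasets()`), each row one outcome measure of one intervention arm
of one primary study, with group sizes and a correlation-scale effect
size `r` (positive = intervention better; depression scales are
sign-flipped at extraction).  The estimand of each meta-analysis is the
mean true correlation between receiving a positive psychology
intervention and the outcome, in the presence of between-study
heterogeneity and plausible selection for significance.

## From rows to one effect per study

**Coding rules** (`apply_coding_rules()`): rows whose source reported too
little to compute an effect (`r = NA`) are excluded and logged — the
bundled tables carry no raw summary statistics from which imputation
would be possible, so exclusion is the only path.  When only a total N
is printed, group sizes are imputed by equal split, the odd participant
going to the treatment group (a deterministic, documented convention).
Four articles that report conditions of one underlying study are merged
under one study id while retaining their article ids, so each article's
control group is still attributed correctly.

**Sampling variances.** Every per-row variance comes from the standard
two-group conversion chain: `d = sqrt(a) r / sqrt(1 - r^2)` with
`a = (n_t + n_c)^2 / (n_t n_c)`, `var(d) = (n_t+n_c)/(n_t n_c) +
d^2/(2(n_t+n_c))`, propagated back to r and then to Fisher z, where it
collapses to the closed form `(1 - r^2/2)/n` — close to the common
`1/(n-3)` shortcut (available as `var_method = "fisher"`) for small
effects but smaller for large ones, which is what this literature's
small, large-effect studies make consequential.  In multi-arm
studies the printed per-row totals count the shared control group once
per arm; we divide the control n by the number of arms of its article
inside the variance (the standard shared-group correction), so a
five-arm study cannot claim five copies of its control group's
information.  An optional Hedges small-sample correction on d
(`hedges_g`) is off by default: the tabulated effect sizes are
uncorrected conversions.

**Composites.** Outcomes and arms are collapsed with the Schmidt–Hunter
composite: point estimate the arithmetic mean (on the z scale), variance
`(1/m^2) * sum_ij rho_ij sqrt(V_i V_j)` with the within-study
correlation imputed at `within_r = .50` for every pair of distinct
effects — the conventional default when primary studies do not report
outcome intercorrelations, applied to arm pairs as well (they share a
control group and a sample frame).  The composite estimate always lies
within the range of its inputs; its variance is non-increasing in the
number of outcomes and non-decreasing in `within_r`.  A study's
`n_eff = 3 + 1/var_z` is the variance-equivalent N actually used in
weighting; `n_total` (treatment groups plus each control once) is kept
for description.  Correlated outcomes and shared controls mean
`n_eff < n_total`, by design.

## Pooling and heterogeneity

Pooling is inverse-variance on the Fisher-z scale.  The default `tau^2`
is DerSimonian–Laird (Paule–Mandel and REML are options), confidence
limits are plain Wald on z and back-transformed — no Knapp–Hartung
adjustment, matching the width of the published intervals.  `I^2` is
Q-based, `max(0, (Q - df)/Q) * 100`, hence identical across `tau^2`
estimators.

## Small-study diagnostics and adjustment

- **Egger test** (`egger_test`): classical unweighted OLS of `z_i/se_i`
  on `1/se_i`, intercept t-test on k−2 df — the df printed throughout the
  source results (e.g. t(38) with k = 40) identify this variant; the
  weighted meta-regression form is an option.
- **Trim-and-fill** (`trim_and_fill`): Duval–Tweedie with the L0
  estimator, side auto-selected from the Egger intercept sign, mirror
  images filled and the adjusted estimate re-pooled under random
  effects.  Observed studies are never dropped from the final pool.
- **Cumulative meta-analysis** (`cumulative_meta`): most-precise-first,
  final prefix equal to the full pool.
- **TOP10** (`top10`): fixed-effect pool of the `ceil(k/10)` most
  precise studies; precision ties break by study id.
- **Limit meta-analysis** (`limit_meta`): the extended random-effects
  model `z_i = b0 + b1 x_i + x_i e_i`, `x_i = sqrt(v_i + tau^2)`, fitted
  by weighted least squares with weights `1/x_i^2` (ordinary least
  squares on the generalized radial plot).  As a study's sampling
  variance tends to zero, `x_i` tends to `tau`, so the bias-adjusted
  estimate is the expectation `b0 + b1*tau`; its standard error uses the
  unscaled coefficient covariance (unit radial errors under the model),
  which reproduces the published interval widths.  The raw intercept and
  a fixed-effect pool of the shrunken estimates
  `mu + G_i (z_i - mu)`, `G_i = sqrt(tau^2/(v_i + tau^2))`, are exposed
  as alternative adjustments.  Cochran's Q decomposes exactly into a
  1-df small-study component `Q - Q'` and the (k−2)-df residual `Q'` of
  the extended fit.  When `tau^2 = 0` there is nothing to shrink and the
  function returns the fixed-effect estimate with a note.

**Outliers** (`detect_outliers_iqr`): study effects beyond 1.5×IQR from
the quartiles of the study-level r distribution, quartiles by linear
interpolation (type 7).  The deleted-residual rule (leave-one-out
random-effects fits, |t| > 1.96) is provided as the corroborating
method.  `sensitivity_rerun` repeats the full battery without the
flagged studies.

## Choices the source analysis leaves unstated

The publication being replicated names its toolchain but not the exact
estimator variants.  `estimator_sweep()` documents how the results move
across the open choices; the package defaults are the combination that
best reproduces the printed values while remaining a single coherent
pipeline:

| choice | default | alternatives |
|---|---|---|
| per-row variance | d↔r conversion chain | `1/(n-3)` |
| shared control in multi-arm studies | split across arms | full n per row |
| composite correlation | .50 | any in [0, 1) |
| `tau^2` | DerSimonian–Laird | PM, REML |
| Egger variant | classical OLS | weighted |
| limit-meta adjustment | expectation `b0 + b1*tau` | intercept, shrunken pool |

With these defaults the pipeline reproduces, within ±.02 on pooled r and
±.03 on limit-meta estimates, the published k, pooled correlations and
confidence limits, Egger t for the well-being set, the limit-adjusted
estimates of all five replications, and the depression outlier flag
(`Seligman.2006.2`).  Two quantities resist any single coherent variant
we examined: the printed I² values for two of the study sets sit 2–4
points outside our ±3-point band (conventions that match them degrade
the pooled estimates instead), and one printed without-outlier
limit-meta estimate differs by ~.03.  The source also contains internal
inconsistencies — an Egger test printed with t(22) and a residual
Q'(22) for a set whose own summary table says k = 25 — suggesting its
bias analyses occasionally ran on a slightly different study set than
its pooling.  We report our values as computed rather than forcing
agreement.

## The synthetic-data generator

`generate_meta_dataset()` emulates the statistical structure the
analysis assumes: true study effects `theta_i ~ N(mu_z, tau^2)` on the z
scale; per-group sizes log-normal with median 25 and log-SD 0.9,
calibrated to the group sizes observed across the bundled tables (median
26, log-SD 0.92) — many small studies, a few large; `m` outcomes per arm
with equicorrelated estimates at `within_r = .50`; multiple arms sharing
one control; and selection for significance modeled as censor-and-redraw
(a study that is not significantly positive is redrawn with probability
`selection`), which keeps k fixed and test behavior stable; truncation
mode is available.  The same seed yields a bit-identical table, and the
output uses the fixture CSV schema so it flows through the identical
pipeline.

What the generator does *not* emulate: questionnaire-level item noise,
non-normal effect distributions, correlation between a study's size and
its true effect, and selection acting at the outcome (rather than study)
level.  Passing tests on synthetic data therefore validate the
estimators under the model's own assumptions, not the realism of those
assumptions.

Simulation checks in the test suite use: parameter recovery at k = 200
per meta-analysis (500 seeds); Egger type-I error at `tau = 0` — the
test's null model; with heterogeneity the classical Egger test is known
to be anticonservative, which would measure that known property rather
than this implementation; limit-meta coverage of a zero effect under
strong selection (`selection = .9`) at k = 50, where the null "all true
effects zero" requires `mu_z = 0, tau = 0` (with `tau > 0`, selection
retains studies whose *true* effects are positive, so even an infinitely
precise study is biased and no funnel-based adjustment targets zero);
and TOP10 at k = 200, the scale at which a "most precise tenth" is a
stable stratum.

## Numerical notes and limitations

Ties in precision are broken by study id everywhere ordering matters, so
results are invariant to row order.  Trim-and-fill iterates the rank
estimator to a fixed point (cap 50 iterations; non-convergence is an
error with the k0 trace).  `tau^2` estimators are bracketed/bisected to
1e-10.  All composites require positive variances; pooling requires
k ≥ 2, Egger and limit meta-analysis k ≥ 3, outlier rules k ≥ 4.  The
pipeline analyzes printed two-decimal effect sizes; the original authors
worked from unrounded values, which contributes irreducible last-digit
disagreement.  Moderator analyses and selection-model estimators
(Copas, p-curve) are out of scope.
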