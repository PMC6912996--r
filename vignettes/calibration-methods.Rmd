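---
title: "Assessing and correcting the calibration of risk prediction models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing and correcting the calibration of risk prediction models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calval)
```

## The problem

A binary risk prediction model outputs, for each subject, a probability
`p̂` of an event. Discrimination — do subjects with the event get higher
`p̂` than those without? — is routinely reported via the c-statistic.
Calibration — can `p̂` be believed as a probability? — is the neglected
half of performance, and the half that decision-making actually rests on: a
model that says "20% risk" when the truth is 10% doubles the number of
patients pushed over a 20% treatment threshold.

`calval` assesses calibration at the three levels that are estimable in
practice, and corrects models that fail.

## Models and estimators

Throughout, predicted risks are clipped to `[1e-10, 1 - 1e-10]` before any
logit transform. Clipping keeps boundary records in the likelihood rather
than dropping them; a warning reports how many were affected. When *all*
risks sit at a boundary while both outcome classes are present, the
likelihood carries no interior information and the estimators refuse with a
"degenerate risks" error.

### Mean calibration

`mean_calibration()` compares the average predicted risk with the event
rate: the O/E ratio, and the maximum-likelihood intercept `c` of the offset
model `logit P(Y=1) = logit(p̂) + c` (slope fixed at 1). The offset
log-likelihood is strictly concave in `c` with derivative
`n(ȳ - mean(p̂_c))` at any `c`, so the estimate's sign is exactly the sign
of `event rate − mean predicted risk` — an invariant the test suite asserts.
The `glm` solution is polished with a few Newton steps so the score equation
`Σ(y − expit(logit(p̂) + c)) = 0` holds to machine precision; this is what
makes the intercept update below conserve the event rate exactly rather
than to optimizer tolerance.

### Weak calibration

`recalibration_fit()` jointly fits `(a, b)` in
`logit P(Y=1) = a + b·logit(p̂)` by maximum likelihood (`stats::glm`),
with standard errors from the observed information and Wald intervals
(default level 0.95 — standard and adequate at validation sample sizes).
Note the two intercepts are different quantities: the offset-model `c`
conditions on slope 1, the joint `a` does not. Both are reported and
labeled; recovery targets in the tests use the joint model, whose `(a, b)`
is the estimand defined by the simulator's distortion construction.

If either estimate exceeds 15 in absolute value on the log-odds scale the
fit is flagged `converged = FALSE`: a logistic MLE drifting past that bound
is diverging under separation, and silent output would be garbage. Constant
predicted risks make the slope non-identifiable and raise an error.

### Moderate calibration

`flexible_curve()` estimates the observed event proportion as a function of
predicted risk:

* **spline** (default): Bernoulli likelihood fit of the outcome on a
  restricted (natural) cubic spline of `logit(p̂)` with 5 knots at the
  0.05, 0.275, 0.5, 0.725 and 0.95 quantiles — the conventional default in
  the validation literature. The band maps the linear predictor's Wald
  interval through the inverse logit, so it automatically respects `[0, 1]`.
* **loess**: local-linear regression of the 0/1 outcome on `p̂`, tricube
  weights over the nearest `span` fraction of subjects (default 0.75), no
  robustness iterations — they misbehave on binary data. The smoother is
  evaluated explicitly as a linear functional `l(x₀)'y`, which gives
  pointwise standard errors from the equivalent-kernel weights with
  binomial variance `p̂(1−p̂)`; fitted values and the band are truncated to
  `[0, 1]`. The explicit evaluation reproduces `stats::loess` with
  `surface = "direct"` to machine precision (asserted in the tests) while
  remaining able to deliver standard errors at cohort sizes of 10⁵, where
  `stats::loess`'s exact-SE path is computationally infeasible.

The grid is 100 equally spaced points between the 1st and 99th percentiles
of the predicted risks: curves are meaningful only over the supported risk
range, and extrapolated tails mislead. Because the curve is described only
visually in most reports, the object also carries two assertable scalars,
the maximum and mean absolute deviation of the fitted curve from the
diagonal.

With fewer than 50 subjects or fewer than 10 distinct risks the curve
errors and directs the user to weak calibration — in small datasets the
intercept and slope are the defendable assessment, and the report attaches
a warning whenever there are fewer than 200 events or 200 non-events, the
suggested minimum for a precise curve.

`curve_band_coverage()` validates the band construction by simulation:
the fraction of replicates in which the true calibration curve lies inside
the band at the interior grid point nearest the median risk.

### The Hosmer–Lemeshow test, and why its null simulation refits

`hosmer_lemeshow()` is opt-in and always carries a caveat: the test depends
on an arbitrary grouping, its P value says nothing about the direction or
size of miscalibration, and it has low power. Grouping is deterministic —
quantile boundaries on the predicted risks, tied values to the lower group,
empty groups merged downward — and the statistic
`Σ (O_g − E_g)² / (E_g(1 − E_g/n_g))` is referred to chi-square on
`groups − 2` degrees of freedom.

Those degrees of freedom presume that the probabilities under test were
estimated (two parameters) on the same data. Applied to externally supplied
true probabilities the statistic has approximately `groups` degrees of
freedom, and the `g − 2` reference over-rejects (we measure roughly 9%
rejection at the 5% level). The package's type-I-error check therefore
recalibrates (intercept + slope) on each simulated cohort before applying
the test, which is the setting the reference distribution describes; there
the empirical rejection rate is compatible with 5%. This is worth knowing
when applying the test at external validation — one more reason it is
discouraged.

## The updating ladder

* `update_intercept()` shifts every risk by the offset-model `c`. Its score
  equation forces `mean(updated risk) = event rate` exactly — the same
  identity that makes calibration-in-the-large trivially perfect at
  internal validation.
* `recalibrate()` applies the fitted `(a, b)`. It is idempotent: refitting
  on the updated risks returns `(0, 1)` to optimizer tolerance. A negative
  fitted slope is allowed through but flagged — such a model ranks patients
  worse than chance, and no monotone correction can fix ranking.
* `refit_model()` discards the original coefficients and refits the
  logistic model on the dataset's covariates. A guard requires at least 8
  events and 8 non-events per coefficient (configurable); the number is a
  documented package default operationalizing "re-estimating a model
  requires sufficient data", not a literature constant. Rank-deficient
  covariate matrices are rejected with the collinear columns named.

Both intercept update and recalibration (with positive slope) are strictly
monotone maps, so they cannot change the c-statistic — asserted exactly in
the tests.

`recommend_update()` encodes the choice as an advisory, deterministic CI
rule: slope CI containing 1 with intercept CI excluding 0 → intercept
update; slope CI excluding 1 → recalibration, plus refit when covariates
and the sample-size guard allow; both CIs covering their targets → no
update. It never applies an update itself; the thresholds are a documented
convention, since no universal cut-off for "poorly calibrated" exists.

## What the synthetic cohorts emulate

`generate_binormal()` draws `y ~ Bernoulli(π)`, a marker
`x ~ N(δ·y, 1)` with `δ = √2·Φ⁻¹(AUC)`, and sets the exact posterior
`logit p = logit π + δx − δ²/2`. The equal-variance binormal model is
chosen as a construction because it links the target c-statistic to the
risk distribution in closed form; the generated model is perfectly
calibrated by design. `inject_miscalibration()` then distorts the
*reported* risks via `logit(reported) = (logit(true) − a)/b` while outcomes
continue to follow the true risks — exactly the situation of a model
meeting a new population, and making `(a, b)` the estimand of the
recalibration fit by construction. `generate_covariate_cohort()` supplies
logistic-model cohorts (standard-normal covariates, intercept solved so the
mean risk hits the target prevalence within 1e-6) for refit testing.

`scenario_presets()` ships five archetypes at 25% prevalence and AUC 0.71:
over- and underestimation (`a = ∓1`, `b = 1`), too-extreme and too-moderate
risks (`b = 0.6` and `1.6`, `a = 0`), and a combined scenario
(`a = −1.04`, `b = 0.63`). The distortion magnitudes are package defaults
chosen to make each archetype unmistakable at moderate sample sizes.

What these simulations do *not* emulate: covariate-specific miscalibration
(so passing recovery tests says nothing about strong calibration),
measurement error, case-mix heterogeneity, or population drift — only the
linear-logit calibration *consequences* of such mechanisms. A real
validation can show a wiggly calibration curve with `(a, b) ≈ (0, 1)`;
intercept and slope near target do not guarantee a diagonal curve. The
spline curve and the recalibration line agree (within 0.02 at n = 10⁵ in
the tests) only because the injected distortion is exactly linear on the
logit scale.

## Problem sizes and tolerances

Stochastic checks fix seeds and use 3-standard-error tolerances. Recovery
checks run at n = 100,000 (Monte Carlo SEs of ~0.005 on the slope);
generator fidelity at n = 50,000; band coverage with 500 replicates of
n = 5,000; the Hosmer–Lemeshow null with 1,000 replicates of n = 1,000.
Exact properties — the intercept sign rule, event-rate conservation after
intercept update and refit, c-statistic invariance under monotone maps —
are asserted without tolerance, and the likelihood fits are checked against
brute-force grid maximizers at the grid resolution on small datasets.

## Known limitations

Binary outcomes only: no survival/time-to-event calibration. No net-benefit
or decision-curve analysis. No penalized or continuously updating
strategies — the ladder stops at full refitting. The loess band is a
pointwise Wald band from the equivalent-kernel weights; it is not
simultaneous, and neither band accounts for the data-driven choice of
smoothing parameters.
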