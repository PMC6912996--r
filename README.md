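# calval

Calibration assessment and updating of clinical risk prediction models.

A risk prediction model can rank patients well (high AUC) and still report
risks that are systematically wrong — too high for everyone, or too extreme
at both ends. Such a model misleads patients and clinicians even though its
discrimination looks fine. `calval` is for anyone validating a binary-outcome
risk model on new data: it quantifies how far the predicted risks are from
the observed event proportions, and corrects the model when they disagree.

## What it computes

Calibration is assessed at three workable levels of a four-level hierarchy
(the fourth, *strong* calibration — a correct risk for every covariate
pattern — is a theoretical ideal, not an assessment target):

* **Mean calibration (calibration-in-the-large).** The observed/expected
  ratio O/E, and the intercept `c` of the offset logistic model
  `logit P(Y=1) = logit(p̂) + c` with the slope fixed at 1. Target `c = 0`;
  `c < 0` means general overestimation, `c > 0` underestimation.
* **Weak calibration.** The jointly fitted calibration intercept `a` and
  slope `b` of the logistic recalibration model
  `logit P(Y=1) = a + b · logit(p̂)`. Targets `(a, b) = (0, 1)`; `b < 1`
  means the risks are too extreme (the signature of overfitting), `b > 1`
  too moderate.
* **Moderate calibration.** A flexible calibration curve — observed event
  proportion as a function of predicted risk — fitted with a natural cubic
  spline on the logit scale or a local-linear (loess-type) smoother, with
  pointwise confidence bands, never extrapolated beyond the supported risk
  range.

Discrimination (the c-statistic, by pair counting with ties at 1/2)
accompanies every report, and the Hosmer–Lemeshow test is available on
explicit request only — its result always carries a caveat explaining why
the intercept, slope and curve are preferred.

Miscalibrated models are corrected along the updating ladder:
intercept update (`update_intercept`), logistic recalibration
(`recalibrate`), or full coefficient refit (`refit_model`), with
`recommend_update()` encoding the CI-based choice between them. A binormal
cohort simulator (`generate_binormal`, `inject_miscalibration`) produces
datasets with known prevalence, AUC and distortion so every estimator can be
checked by parameter recovery.

## Worked example

Simulate an external validation cohort of 4888 patients with 44% prevalence
and AUC 0.71, whose reported risks are distorted (overestimated and overly
extreme), then assess it:

```r
library(calval)
ds <- generate_binormal(generator_config(4888, 0.44, 0.71, seed = 2026))
dm <- inject_miscalibration(ds, miscalibration_params(-1.04, 0.63))
report <- assess_calibration(dm)
report
```

```
Calibration report (n = 4888 ; 2122 events )

-- Mean calibration --
Mean calibration
  observed events 2122, expected 3473.84  (O/E = 0.611)
  event rate 0.4341 vs mean predicted risk 0.7107
  calibration-in-the-large intercept -1.564 (95% CI -1.630 to -1.498); target 0

-- Weak calibration --
Logistic recalibration fit (n = 4888 )
  intercept -1.080 (95% CI -1.172 to -0.988); target 0
  slope     0.640 (95% CI 0.588 to 0.691); target 1

-- Moderate calibration --
Flexible calibration curve (spline), 100 grid points on [0.128, 0.988]
  deviation from diagonal: max 0.3527, mean 0.2358

-- Discrimination --
  c-statistic 0.7160 (SE 0.0075, 95% CI 0.7013 to 0.7307)
```

Reading the output: only 0.61 events are observed for every expected event
and the calibration-in-the-large intercept is well below 0, so the model
overestimates risk across the board; the slope of 0.64 says the risks are
also too spread out. The recalibration fit recovers the injected distortion
(−1.04, 0.63) within its confidence intervals. The advisory rule agrees:

```r
recommend_update(report, dm)$recommendation
#> [1] "recalibration"
```

`plot_calibration(report, dm, "calibration.png")` draws the curve with its
band, the ideal diagonal, and back-to-back histograms of the predicted risks
for subjects with and without the event. A command-line interface with
`assess`, `simulate`, `update` and `curve` subcommands is installed at
`inst/cli/calval`.

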