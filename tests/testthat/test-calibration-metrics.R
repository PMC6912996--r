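test_that("mean calibration matches arithmetic and the offset-model oracle", {
  # symmetric case: score at c = 0 vanishes
  ds <- validation_dataset(c(0.5, 0.5), c(0, 1))
  mc <- mean_calibration(ds)
  expect_equal(mc$oe_ratio, 1)
  expect_equal(mc$cil_intercept$estimate, 0, tolerance = 1e-8)

  # overestimation: O/E = 0.5 and a negative intercept
  ds <- validation_dataset(rep(0.5, 4), c(1, 0, 0, 0))
  mc <- mean_calibration(ds)
  expect_equal(mc$observed_events, 1L)
  expect_equal(mc$expected_events, 2)
  expect_equal(mc$oe_ratio, 0.5)
  expect_lt(mc$cil_intercept$estimate, 0)

  # grid-search oracle over c in [-5, 5], step 1e-4
  p <- c(0.2, 0.4, 0.6, 0.8); y <- c(0, 1, 1, 1)
  mc <- mean_calibration(validation_dataset(p, y))
  expect_lt(abs(mc$cil_intercept$estimate - grid_cil_intercept(p, y)), 2e-4)

  expect_error(suppressWarnings(
    mean_calibration(validation_dataset(c(0, 0, 0), c(1, 0, 1)))),
    "degenerate risks")
  expect_warning(mean_calibration(validation_dataset(c(0.3, 0.4), c(0, 0))),
                 "single outcome class")
})

test_that("calibration-in-the-large intercept obeys the sign rule exactly", {
  # concave offset likelihood: derivative at c = 0 is n * (event rate - mean risk)
  for (seed in 1:20) {
    ds <- random_small_ds(40, seed)
    est <- mean_calibration(ds)$cil_intercept$estimate
    gap <- mean(ds$outcome) - mean(ds$predicted_risk)
    if (abs(gap) > 1e-12) expect_identical(sign(est) == sign(gap), TRUE)
  }
  # exact-equality branch: mean predicted equals the event rate
  ds <- validation_dataset(c(0.5, 0.5), c(1, 0))
  expect_equal(mean_calibration(ds)$cil_intercept$estimate, 0,
               tolerance = 1e-8)
})

test_that("recalibration fit matches saturated cases and the 2-D grid oracle", {
  # two risk groups whose observed proportions equal the risks: (a, b) = (0, 1)
  ds <- validation_dataset(rep(c(0.25, 0.75), each = 4),
                           c(1, 0, 0, 0, 1, 1, 1, 0))
  fit <- recalibration_fit(ds)
  expect_equal(fit$intercept$estimate, 0, tolerance = 1e-7)
  expect_equal(fit$slope$estimate, 1, tolerance = 1e-7)
  expect_true(fit$converged)
  expect_true(fit$intercept$ci_low <= 0 && 0 <= fit$intercept$ci_high)

  # independent 2-D likelihood-grid maximizer (absolute grid resolution)
  p <- c(0.1, 0.3, 0.5, 0.7, 0.9); y <- c(0, 0, 1, 0, 1)
  fit <- recalibration_fit(validation_dataset(p, y))
  ab <- grid_recalibration(p, y)
  expect_lt(abs(fit$intercept$estimate - ab[1]), 2e-3)
  expect_lt(abs(fit$slope$estimate - ab[2]), 2e-3)

  # further random small datasets against the oracle
  for (seed in c(11, 12, 13)) {
    ds <- random_small_ds(30, seed)
    fit <- recalibration_fit(ds)
    ab <- grid_recalibration(ds$predicted_risk, ds$outcome)
    expect_lt(abs(fit$intercept$estimate - ab[1]), 2e-3)
    expect_lt(abs(fit$slope$estimate - ab[2]), 2e-3)
  }

  expect_error(recalibration_fit(validation_dataset(rep(0.4, 6),
                                                    c(1, 0, 1, 0, 0, 1))),
               "slope not identifiable")
  expect_error(recalibration_fit(validation_dataset(c(0.2, 0.4), c(0, 0))),
               "at least one event")
})

test_that("separated data are flagged non-converged, not silently reported", {
  p <- c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)
  y <- c(0, 0, 0, 1, 1, 1)
  wrns <- capture_warnings(fit <- recalibration_fit(validation_dataset(p, y)))
  expect_true(any(grepl("non-converged", wrns)))
  expect_false(fit$converged)
  expect_gt(abs(fit$slope$estimate), calval:::SEPARATION_BOUND)
})

test_that("recalibration recovers (0, 1) on a large perfectly calibrated cohort", {
  ds <- perfect_cohort(100000, seed = 21)
  fit <- recalibration_fit(ds)
  expect_lt(abs(fit$slope$estimate - 1), 3 * fit$slope$se)
  expect_lt(abs(fit$intercept$estimate), 3 * fit$intercept$se)
})

test_that("c-statistic counts pairs with ties at 1/2 and is rank-invariant", {
  expect_equal(c_statistic(validation_dataset(c(0.2, 0.8), c(0, 1))), 1)
  expect_equal(c_statistic(validation_dataset(rep(0.4, 4), c(0, 1, 0, 1))), 0.5)
  expect_equal(c_statistic(validation_dataset(c(0.2, 0.6, 0.6), c(0, 1, 0))),
               0.75)
  expect_error(c_statistic(validation_dataset(c(0.2, 0.4), c(1, 1))),
               "undefined")

  # exhaustive pair-counting oracle and invariance under monotone transforms
  monotone_maps <- list(function(p) p^3,
                        function(p) plogis(5 * qlogis(p)),
                        function(p) sqrt(p),
                        function(p) 0.001 + 0.998 * p)
  for (seed in 1:5) {
    ds <- random_small_ds(25, seed)
    pe <- ds$predicted_risk[ds$outcome == 1]
    pn <- ds$predicted_risk[ds$outcome == 0]
    pairs <- outer(pe, pn, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(c_statistic(ds), mean(pairs))
    for (f in monotone_maps) {
      ds2 <- validation_dataset(f(ds$predicted_risk), ds$outcome)
      expect_equal(c_statistic(ds2), c_statistic(ds), tolerance = 1e-12)
    }
  }
})

test_that("c-statistic agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  ds <- random_small_ds(200, 31)
  ref <- as.numeric(pROC::auc(pROC::roc(ds$outcome, ds$predicted_risk,
                                        quiet = TRUE, direction = "<")))
  expect_equal(c_statistic(ds), ref, tolerance = 1e-12)
})

test_that("Hosmer-Lemeshow grouping, statistic and caveat behave as specified", {
  # three saturated strata: O = E in every group, statistic exactly 0
  p <- rep(c(0.25, 0.5, 0.75), each = 4)
  y <- c(1, 0, 0, 0, 1, 1, 0, 0, 1, 1, 1, 0)
  hl <- hosmer_lemeshow(validation_dataset(p, y), groups = 3)
  expect_equal(hl$statistic, 0, tolerance = 1e-12)
  expect_equal(hl$df, hl$groups - 2L)
  expect_match(hl$warning_text, "grouping")

  ds <- random_small_ds(100, 41)
  hl <- hosmer_lemeshow(ds)
  expect_gte(hl$statistic, 0)
  expect_equal(hl$df, hl$groups - 2L)
  expect_true(hl$p_value >= 0 && hl$p_value <= 1)

  expect_error(hosmer_lemeshow(ds, groups = 2), "cannot form groups")
  expect_error(hosmer_lemeshow(random_small_ds(20, 42), groups = 30),
               "cannot form groups")
  expect_error(hosmer_lemeshow(validation_dataset(rep(c(0.3, 0.6), 10),
                                                  rep(c(0, 1), 10))),
               "cannot form groups")
})

test_that("assessment report degrades gracefully and applies the 200/200 rule", {
  # 150 events / 5000 non-events: warning citing the 200-per-class minimum
  set.seed(51)
  n1 <- 150; n0 <- 5000
  p <- c(runif(n1, 0.2, 0.8), runif(n0, 0.01, 0.4))
  y <- rep(c(1L, 0L), c(n1, n0))
  rep1 <- assess_calibration(validation_dataset(p, y))
  expect_true(any(grepl("200", rep1$warnings)))

  # 250 events and 250 non-events: no sample-size warning
  ds <- perfect_cohort(500, prevalence = 0.5, auc = 0.75, seed = 52)
  stopifnot(ds$n_events >= 200, ds$n_nonevents >= 200)
  rep2 <- assess_calibration(ds)
  expect_length(rep2$warnings, 0)

  # constant risks: mean calibration present, slope section marked inestimable
  ds <- validation_dataset(rep(0.3, 300), rbinom(300, 1, 0.3))
  rep3 <- assess_calibration(ds)
  expect_s3_class(rep3$mean, "mean_calibration")
  expect_s3_class(rep3$weak, "not_estimable")
  expect_match(rep3$weak$reason, "not identifiable")

  # Hosmer-Lemeshow appears only on request
  expect_null(rep2$hosmer_lemeshow)
  rep4 <- assess_calibration(perfect_cohort(1000, seed = 53), include_hl = TRUE)
  expect_s3_class(rep4$hosmer_lemeshow, "hl_result")
})
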