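#' Mean calibration (calibration-in-the-large)
#'
#' Compares the average predicted risk with the overall event rate. Two
#' summaries are returned: the observed/expected ratio, and the intercept of
#' the offset logistic model `logit(P(event)) = logit(p_hat) + c` with the
#' slope fixed at 1. A negative intercept indicates general overestimation of
#' risk, a positive one underestimation.
#'
#' @param ds A [validation_dataset()].
#' @param level Confidence level for the intercept's Wald interval.
#' @return An object of class `mean_calibration` with elements
#'   `observed_events`, `expected_events`, `oe_ratio`, `event_rate`,
#'   `mean_predicted` and `cil_intercept` (an `estimate_ci`, or `NULL` with a
#'   warning when only one outcome class is present).
#'
#' @examples
#' ds <- validation_dataset(c(0.5, 0.5, 0.5, 0.5), c(1, 0, 0, 0))
#' mean_calibration(ds)$oe_ratio  # 0.5: risks overestimate
#' @export
mean_calibration <- function(ds, level = 0.95) {
  stopifnot(inherits(ds, "validation_dataset"))
  if (ds$n == 0) stop("no records", call. = FALSE)
  p <- clip_risk(ds$predicted_risk)
  check_not_degenerate(p)
  observed <- ds$n_events
  expected <- sum(ds$predicted_risk)
  cil <- NULL
  if (ds$n_events == 0 || ds$n_nonevents == 0) {
    warning("single outcome class: calibration-in-the-large intercept omitted",
            call. = FALSE)
  } else {
    lp <- logit(p)
    fit <- stats::glm(ds$outcome ~ 1, family = stats::binomial(),
                      offset = lp)
    # Newton-polish the offset-model MLE so the score equation
    # sum(y - expit(lp + c)) = 0 holds to machine precision: the intercept
    # update inherits mean(updated risk) = event rate exactly
    c_hat <- stats::coef(fit)[[1]]
    for (i in 1:8) {
      mu <- expit(lp + c_hat)
      score <- sum(ds$outcome - mu)
      info <- sum(mu * (1 - mu))
      step <- score / info
      c_hat <- c_hat + step
      if (abs(step) < 1e-14) break
    }
    mu <- expit(lp + c_hat)
    cil <- wald_ci(c_hat, 1 / sqrt(sum(mu * (1 - mu))), level)
  }
  structure(
    list(
      observed_events = observed,
      expected_events = expected,
      oe_ratio = if (expected > 0) observed / expected else NA_real_,
      event_rate = mean(ds$outcome),
      mean_predicted = mean(ds$predicted_risk),
      cil_intercept = cil
    ),
    class = "mean_calibration"
  )
}

#' @export
print.mean_calibration <- function(x, ...) {
  cat("Mean calibration\n")
  cat(sprintf("  observed events %d, expected %.2f  (O/E = %.3f)\n",
              x$observed_events, x$expected_events, x$oe_ratio))
  cat(sprintf("  event rate %.4f vs mean predicted risk %.4f\n",
              x$event_rate, x$mean_predicted))
  if (!is.null(x$cil_intercept)) {
    cat(sprintf("  calibration-in-the-large intercept %.3f (%.0f%% CI %.3f to %.3f); target 0\n",
                x$cil_intercept$estimate, 100 * x$cil_intercept$level,
                x$cil_intercept$ci_low, x$cil_intercept$ci_high))
  }
  invisible(x)
}

wald_ci <- function(estimate, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(
    list(estimate = unname(estimate), se = unname(se),
         ci_low = unname(estimate - z * se),
         ci_high = unname(estimate + z * se), level = level),
    class = "estimate_ci"
  )
}

#' @export
print.estimate_ci <- function(x, ...) {
  cat(sprintf("%.4f (SE %.4f, %.0f%% CI %.4f to %.4f)\n",
              x$estimate, x$se, 100 * x$level, x$ci_low, x$ci_high))
  invisible(x)
}

# Divergence bound for the logistic recalibration fit: beyond this the MLE is
# drifting to infinity (separation) and Wald output is meaningless.
SEPARATION_BOUND <- 15

#' Logistic recalibration fit (calibration intercept and slope)
#'
#' Jointly fits intercept `a` and slope `b` of the recalibration model
#' `logit(P(event)) = a + b * logit(p_hat)` by maximum likelihood. For a well
#' calibrated model the targets are `a = 0` and `b = 1`. A slope below 1 means
#' the predicted risks are too extreme (typical of overfitting); above 1, too
#' moderate. This joint intercept is distinct from the calibration-in-the-large
#' intercept of [mean_calibration()], which fixes the slope at 1.
#'
#' @param ds A [validation_dataset()].
#' @param level Confidence level for Wald intervals.
#' @return An object of class `recalibration_fit`: `intercept` and `slope`
#'   (`estimate_ci` objects with SEs from the observed information), `loglik`,
#'   `converged`, `n_used`. `converged` is `FALSE` when either estimate
#'   exceeds 15 in absolute value on the log-odds scale (separation guard).
#'
#' @examples
#' ds <- validation_dataset(rep(c(0.25, 0.75), each = 4),
#'                          c(1, 0, 0, 0, 1, 1, 1, 0))
#' fit <- recalibration_fit(ds)
#' c(fit$intercept$estimate, fit$slope$estimate)  # exactly (0, 1)
#' @export
recalibration_fit <- function(ds, level = 0.95) {
  stopifnot(inherits(ds, "validation_dataset"))
  check_two_classes(ds, "recalibration")
  p <- clip_risk(ds$predicted_risk)
  lp <- logit(p)
  if (length(unique(lp)) < 2) {
    stop("slope not identifiable: predicted risks are constant", call. = FALSE)
  }
  fit <- stats::glm(ds$outcome ~ lp, family = stats::binomial())
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  converged <- isTRUE(fit$converged) && all(abs(co) <= SEPARATION_BOUND)
  if (!converged) {
    warning("recalibration fit flagged non-converged (possible separation)",
            call. = FALSE)
  }
  structure(
    list(
      intercept = wald_ci(co[[1]], se[[1]], level),
      slope = wald_ci(co[[2]], se[[2]], level),
      loglik = as.numeric(stats::logLik(fit)),
      converged = converged,
      n_used = ds$n
    ),
    class = "recalibration_fit"
  )
}

#' @export
print.recalibration_fit <- function(x, ...) {
  cat("Logistic recalibration fit (n =", x$n_used, ")\n")
  cat(sprintf("  intercept %.3f (%.0f%% CI %.3f to %.3f); target 0\n",
              x$intercept$estimate, 100 * x$intercept$level,
              x$intercept$ci_low, x$intercept$ci_high))
  cat(sprintf("  slope     %.3f (%.0f%% CI %.3f to %.3f); target 1\n",
              x$slope$estimate, 100 * x$slope$level,
              x$slope$ci_low, x$slope$ci_high))
  if (!x$converged) cat("  WARNING: fit did not converge (separation?)\n")
  invisible(x)
}

#' Concordance statistic (c-statistic / AUC)
#'
#' The probability that a randomly chosen subject with the event received a
#' higher predicted risk than a randomly chosen subject without it, ties
#' counted 1/2. Computed by midranks, which equals exhaustive pair counting.
#' Invariant under strictly increasing transforms of the predicted risk.
#'
#' @param ds A [validation_dataset()].
#' @return A number in \[0, 1\].
#' @examples
#' c_statistic(validation_dataset(c(0.2, 0.6, 0.6), c(0, 1, 0)))  # 0.75
#' @export
c_statistic <- function(ds) {
  stopifnot(inherits(ds, "validation_dataset"))
  if (ds$n_events == 0 || ds$n_nonevents == 0) {
    stop("c-statistic undefined: only one outcome class present", call. = FALSE)
  }
  r <- rank(ds$predicted_risk)  # midranks score tied pairs 1/2
  n1 <- ds$n_events
  (sum(r[ds$outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * ds$n_nonevents)
}

HL_CAVEAT <- paste(
  "The Hosmer-Lemeshow test is reported for completeness only: it depends on",
  "an artificial grouping of patients into risk strata, its P value says",
  "nothing about the type or extent of miscalibration, and it has low power.",
  "Prefer the calibration intercept, slope and flexible calibration curve."
)

#' Hosmer-Lemeshow goodness-of-fit test (discouraged)
#'
#' Partitions subjects into quantile groups of predicted risk and compares
#' observed with expected events per group. Provided because the test is still
#' widely requested; the result always carries a caveat recommending against
#' it. Tied risk values go to the lower group and empty groups are merged
#' downward, so the grouping is deterministic.
#'
#' @param ds A [validation_dataset()].
#' @param groups Number of risk strata (default 10 deciles; minimum 3).
#' @return An object of class `hl_result`: `statistic`, `df` (= groups - 2),
#'   `p_value`, `groups` (number actually formed), `warning_text`.
#' @export
hosmer_lemeshow <- function(ds, groups = 10L) {
  stopifnot(inherits(ds, "validation_dataset"))
  groups <- as.integer(groups)
  if (groups < 3L) {
    stop("cannot form groups: at least 3 risk strata are required", call. = FALSE)
  }
  if (ds$n < groups) {
    stop("cannot form groups: fewer subjects than requested groups", call. = FALSE)
  }
  p <- ds$predicted_risk
  breaks <- unique(stats::quantile(p, probs = seq(0, 1, length.out = groups + 1),
                                   names = FALSE))
  if (length(breaks) < 4L) {
    stop("cannot form groups: too few distinct predicted risks", call. = FALSE)
  }
  # right-closed intervals: a value equal to an internal boundary falls in the
  # lower group; duplicate quantiles already merged via unique()
  g <- cut(p, breaks = breaks, include.lowest = TRUE, right = TRUE)
  n_g <- tabulate(g, nbins = nlevels(g))
  keep <- n_g > 0
  O <- tapply(ds$outcome, g, sum)[keep]
  E <- tapply(p, g, sum)[keep]
  n_g <- n_g[keep]
  k <- sum(keep)
  if (k < 3L) {
    stop("cannot form groups: too few non-empty risk strata", call. = FALSE)
  }
  stat <- sum((O - E)^2 / (E * (1 - E / n_g)))
  df <- k - 2L
  structure(
    list(statistic = unname(stat), df = df,
         p_value = stats::pchisq(stat, df, lower.tail = FALSE),
         groups = k, warning_text = HL_CAVEAT),
    class = "hl_result"
  )
}

#' @export
print.hl_result <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow: chi-square %.3f on %d df (groups = %d), P = %.4f\n",
              x$statistic, x$df, x$groups, x$p_value))
  cat(strwrap(x$warning_text, prefix = "  "), sep = "\n")
  invisible(x)
}
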