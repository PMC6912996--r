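#' Intercept update (correct calibration-in-the-large)
#'
#' The first rung of the updating ladder: shifts every predicted risk by a
#' constant on the log-odds scale, `logit(updated) = logit(p_hat) + c`, with
#' `c` the maximum-likelihood intercept of the offset logistic model. The MLE
#' score equation forces the mean updated risk to equal the event rate
#' exactly, so the updated model is mean-calibrated in the validation sample.
#'
#' @param ds A [validation_dataset()].
#' @param level Confidence level for the correction's Wald interval.
#' @return An object of class `update_result` with `method =
#'   "intercept_update"`, the per-subject `updated_risk`, `params` (the fitted
#'   shift `c` as an `estimate_ci`), and `diagnostics` (a
#'   [recalibration_fit()] of the updated risks).
#' @export
update_intercept <- function(ds, level = 0.95) {
  stopifnot(inherits(ds, "validation_dataset"))
  check_two_classes(ds, "intercept update")
  mc <- mean_calibration(ds, level = level)
  c_hat <- mc$cil_intercept$estimate
  lp <- logit(clip_risk(ds$predicted_risk, warn = FALSE))
  updated <- expit(lp + c_hat)
  new_update_result("intercept_update", ds, updated,
                    params = list(c = mc$cil_intercept))
}

#' Logistic recalibration update
#'
#' The second rung: rescales the predicted risks with the jointly fitted
#' calibration intercept and slope, `logit(updated) = a + b * logit(p_hat)`.
#' Idempotent up to optimizer tolerance: refitting the recalibration model on
#' the updated risks returns (0, 1). A negative fitted slope is allowed to
#' proceed but is flagged — such a model ranks patients backwards and no
#' recalibration can rescue it.
#'
#' @param ds A [validation_dataset()].
#' @param level Confidence level for the Wald intervals.
#' @return An `update_result` with `method = "recalibration"`, the updated
#'   risks, `params` (the [recalibration_fit()] used), and `diagnostics`.
#' @export
recalibrate <- function(ds, level = 0.95) {
  stopifnot(inherits(ds, "validation_dataset"))
  fit <- recalibration_fit(ds, level = level)
  b <- fit$slope$estimate
  flags <- character(0)
  if (b < 0) {
    flags <- paste("fitted calibration slope is negative: the model ranks",
                   "patients worse than chance and updating cannot rescue",
                   "its ranking")
    warning(flags, call. = FALSE)
  }
  lp <- logit(clip_risk(ds$predicted_risk, warn = FALSE))
  updated <- expit(fit$intercept$estimate + b * lp)
  new_update_result("recalibration", ds, updated, params = fit, flags = flags)
}

#' Full model refit
#'
#' The top rung of the updating ladder: re-estimates all coefficients by
#' fitting a maximum-likelihood logistic regression of the outcome on the
#' dataset's covariates, discarding the original model. Appropriate when the
#' validation sample is relatively large; a configurable guard requires at
#' least `min_epv` events and `min_epv` non-events per estimated coefficient.
#' The intercept score equation makes the mean fitted risk equal the event
#' rate exactly, the hallmark of internal validation.
#'
#' @param ds A [validation_dataset()] carrying a full-column-rank covariate
#'   matrix.
#' @param min_epv Minimum events (and non-events) per coefficient (default 8).
#' @param level Confidence level for coefficient Wald intervals.
#' @return An `update_result` with `method = "refit"`, the fitted risks,
#'   `params` (a `logistic_model`: intercept and named coefficients, with SEs),
#'   and `diagnostics`.
#' @export
refit_model <- function(ds, min_epv = 8, level = 0.95) {
  stopifnot(inherits(ds, "validation_dataset"))
  check_two_classes(ds, "refit")
  X <- ds$covariates
  if (is.null(X)) stop("refit requires a covariate matrix", call. = FALSE)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    dropped <- setdiff(seq_len(ncol(X) + 1L), qrX$pivot[seq_len(qrX$rank)])
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(c("(intercept)", colnames(X))[dropped], collapse = ", "),
         call. = FALSE)
  }
  k <- ncol(X) + 1L
  if (ds$n_events < min_epv * k || ds$n_nonevents < min_epv * k) {
    stop("refitting ", k, " coefficients needs at least ", min_epv * k,
         " events and as many non-events (re-estimating a model entirely ",
         "requires sufficient data; small samples invite overfitting)",
         call. = FALSE)
  }
  df <- data.frame(y = ds$outcome, X, check.names = FALSE)
  fit <- stats::glm(y ~ ., family = stats::binomial(), data = df)
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  model <- structure(
    list(intercept = wald_ci(co[[1]], se[[1]], level),
         coefficients = co[-1], coefficient_se = se[-1],
         covariate_names = colnames(X)),
    class = "logistic_model"
  )
  new_update_result("refit", ds, unname(stats::fitted(fit)), params = model)
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("Logistic model: intercept", sprintf("%.4f", x$intercept$estimate), "\n")
  for (i in seq_along(x$coefficients)) {
    cat(sprintf("  %-14s %8.4f (SE %.4f)\n", x$covariate_names[i],
                x$coefficients[[i]], x$coefficient_se[[i]]))
  }
  invisible(x)
}

new_update_result <- function(method, ds, updated_risk, params,
                              flags = character(0)) {
  ds_upd <- validation_dataset(predicted_risk = updated_risk,
                               outcome = ds$outcome,
                               true_risk = ds$true_risk,
                               covariates = ds$covariates, id = ds$id)
  diagnostics <- tryCatch(suppressWarnings(recalibration_fit(ds_upd)),
                          error = function(e) NULL)
  structure(
    list(method = method, updated_risk = updated_risk, params = params,
         diagnostics = diagnostics, flags = flags, n = ds$n),
    class = "update_result"
  )
}

#' @export
print.update_result <- function(x, ...) {
  cat("Model update:", x$method, "(n =", x$n, ")\n")
  if (x$method == "intercept_update") {
    cat(sprintf("  correction c = %.4f on the log-odds scale\n",
                x$params$c$estimate))
  } else if (x$method == "recalibration") {
    cat(sprintf("  a = %.4f, b = %.4f\n", x$params$intercept$estimate,
                x$params$slope$estimate))
  }
  if (!is.null(x$diagnostics)) {
    cat(sprintf("  post-update intercept %.4f, slope %.4f\n",
                x$diagnostics$intercept$estimate, x$diagnostics$slope$estimate))
  }
  for (f in x$flags) cat("  FLAG:", f, "\n")
  invisible(x)
}

#' Recommend an updating strategy from a calibration report
#'
#' A deterministic, advisory rule set (it never applies an update):
#' if the slope CI contains 1 but the calibration-in-the-large intercept CI
#' excludes 0, an intercept update suffices; if the slope CI excludes 1,
#' logistic recalibration is indicated, and full refitting is also offered
#' when covariates are available and the events-per-coefficient guard holds;
#' when both CIs cover their targets no update is indicated.
#'
#' @param report A [assess_calibration()] report.
#' @param ds The underlying [validation_dataset()] (used to check covariate
#'   availability and the refit sample-size guard).
#' @param min_epv Events-per-coefficient guard passed to the refit check.
#' @return A list with `recommendation` (character vector of methods, or
#'   `"none"`) and `rationale` (text).
#' @export
recommend_update <- function(report, ds, min_epv = 8) {
  stopifnot(inherits(report, "calibration_report"))
  fit <- report$weak
  if (is.null(fit) || !inherits(fit, "recalibration_fit")) {
    stop("report carries no intercept/slope estimates", call. = FALSE)
  }
  cil <- report$mean$cil_intercept
  slope_covers_1 <- fit$slope$ci_low <= 1 && 1 <= fit$slope$ci_high
  cil_covers_0 <- cil$ci_low <= 0 && 0 <= cil$ci_high
  refit_ok <- FALSE
  if (!is.null(ds$covariates)) {
    k <- ncol(ds$covariates) + 1L
    refit_ok <- ds$n_events >= min_epv * k && ds$n_nonevents >= min_epv * k
  }
  if (!slope_covers_1) {
    rec <- "recalibration"
    why <- sprintf("calibration slope %.2f with CI excluding 1: risks are too %s; recalibrate intercept and slope",
                   fit$slope$estimate,
                   if (fit$slope$estimate < 1) "extreme" else "moderate")
    if (refit_ok) {
      rec <- c(rec, "refit")
      why <- paste(why, "- covariates and sample size also permit full",
                   "refitting (re-estimating the model entirely requires",
                   "sufficient data)")
    }
  } else if (!cil_covers_0) {
    rec <- "intercept_update"
    why <- sprintf("calibration-in-the-large intercept %.2f with CI excluding 0 but slope compatible with 1: correct the intercept (risks are generally %sestimated)",
                   cil$estimate, if (cil$estimate < 0) "over" else "under")
  } else {
    rec <- "none"
    why <- "no update indicated: intercept CI covers 0 and slope CI covers 1"
  }
  list(recommendation = rec, rationale = why)
}
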