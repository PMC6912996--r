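SAMPLE_SIZE_WARNING <- paste(
  "fewer than 200 events or 200 non-events: flexible calibration curves are",
  "imprecise at this size; a minimum of 200 subjects with and 200 without the",
  "event has been suggested. Weak calibration (intercept and slope) is the",
  "defendable assessment here."
)

#' Assess calibration of a risk prediction model
#'
#' Assembles the full external-validation report: mean calibration (O/E ratio
#' and calibration-in-the-large intercept), weak calibration (recalibration
#' intercept and slope), moderate calibration (flexible calibration curve
#' with diagonal-deviation summaries), and discrimination (c-statistic with a
#' Hanley-McNeil confidence interval). The Hosmer-Lemeshow test is computed
#' only on explicit request and always carries its caveat. Sections that
#' cannot be estimated (e.g. a slope on constant risks) are reported as "not
#' estimable" with the reason instead of aborting the whole report, and a
#' warning is attached when there are fewer than 200 events or 200 non-events.
#'
#' @param ds A [validation_dataset()].
#' @param level Confidence level used throughout.
#' @param curve_method `"spline"` or `"loess"` for the flexible curve.
#' @param include_hl Set `TRUE` to add the (discouraged) Hosmer-Lemeshow test.
#' @param hl_groups Number of risk strata if `include_hl`.
#' @return An object of class `calibration_report` with sections `mean`,
#'   `weak`, `moderate`, `discrimination`, optionally `hosmer_lemeshow`,
#'   plus `warnings` and `metadata`.
#' @export
assess_calibration <- function(ds, level = 0.95,
                               curve_method = c("spline", "loess"),
                               include_hl = FALSE, hl_groups = 10L) {
  stopifnot(inherits(ds, "validation_dataset"))
  curve_method <- match.arg(curve_method)
  section <- function(expr) {
    tryCatch(suppressWarnings(expr), error = function(e) {
      structure(list(reason = conditionMessage(e)), class = "not_estimable")
    })
  }
  warnings <- character(0)
  if (ds$n_events < 200 || ds$n_nonevents < 200) {
    warnings <- c(warnings, SAMPLE_SIZE_WARNING)
  }
  disc <- section({
    cs <- c_statistic(ds)
    se <- hanley_mcneil_se(cs, ds$n_events, ds$n_nonevents)
    ci <- wald_ci(cs, se, level)
    ci$ci_low <- max(ci$ci_low, 0); ci$ci_high <- min(ci$ci_high, 1)
    ci
  })
  report <- structure(
    list(
      mean = section(mean_calibration(ds, level = level)),
      weak = section(recalibration_fit(ds, level = level)),
      moderate = section(flexible_curve(ds, method = curve_method,
                                        level = level)),
      discrimination = disc,
      hosmer_lemeshow = if (include_hl) section(hosmer_lemeshow(ds, hl_groups)),
      warnings = warnings,
      metadata = list(n = ds$n, n_events = ds$n_events,
                      n_nonevents = ds$n_nonevents, level = level,
                      curve_method = curve_method,
                      timestamp = format(Sys.time(), tz = "UTC"))
    ),
    class = "calibration_report"
  )
  report
}

# Hanley-McNeil SE for the c-statistic (binormal-free approximation).
hanley_mcneil_se <- function(auc, n1, n0) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) + (n0 - 1) * (q2 - auc^2)) /
         (n1 * n0))
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("Calibration report (n =", x$metadata$n, ";", x$metadata$n_events,
      "events )\n\n")
  sec <- function(name, obj) {
    cat("--", name, "--\n")
    if (inherits(obj, "not_estimable")) {
      cat("  not estimable:", obj$reason, "\n")
    } else if (!is.null(obj)) print(obj)
    cat("\n")
  }
  sec("Mean calibration", x$mean)
  sec("Weak calibration", x$weak)
  sec("Moderate calibration", x$moderate)
  cat("-- Discrimination --\n")
  if (inherits(x$discrimination, "not_estimable")) {
    cat("  not estimable:", x$discrimination$reason, "\n")
  } else {
    cat("  c-statistic "); print(x$discrimination)
  }
  cat("\n")
  if (!is.null(x$hosmer_lemeshow)) {
    sec("Hosmer-Lemeshow (discouraged)", x$hosmer_lemeshow)
  }
  for (w in x$warnings) cat("WARNING:", strwrap(w, prefix = " "), "\n")
  invisible(x)
}

report_to_list <- function(x) {
  ci_list <- function(e) {
    if (is.null(e)) return(NULL)
    list(estimate = e$estimate, se = e$se, ci_low = e$ci_low,
         ci_high = e$ci_high, level = e$level)
  }
  maybe <- function(obj, f) {
    if (inherits(obj, "not_estimable")) list(not_estimable = obj$reason)
    else if (is.null(obj)) NULL
    else f(obj)
  }
  out <- list(
    oe_ratio = maybe(x$mean, function(m) m$oe_ratio),
    event_rate = maybe(x$mean, function(m) m$event_rate),
    mean_predicted = maybe(x$mean, function(m) m$mean_predicted),
    cil_intercept = maybe(x$mean, function(m) ci_list(m$cil_intercept)),
    intercept = maybe(x$weak, function(w) ci_list(w$intercept)),
    slope = maybe(x$weak, function(w) ci_list(w$slope)),
    curve = maybe(x$moderate, function(cv) {
      list(method = cv$method, grid = cv$grid, fitted = cv$fitted,
           ci_low = cv$ci_low, ci_high = cv$ci_high,
           max_abs_dev = cv$max_abs_dev, mean_abs_dev = cv$mean_abs_dev)
    }),
    c_statistic = maybe(x$discrimination, ci_list),
    warnings = x$warnings,
    metadata = x$metadata
  )
  if (!is.null(x$hosmer_lemeshow)) {
    out$hosmer_lemeshow <- maybe(x$hosmer_lemeshow, function(h) {
      list(statistic = h$statistic, df = h$df, p_value = h$p_value,
           groups = h$groups, warning_text = h$warning_text)
    })
  }
  out
}

#' Serialize a calibration report as JSON
#'
#' Stable key names: `oe_ratio`, `cil_intercept`, `intercept`, `slope`,
#' `curve`, `c_statistic`, `warnings`, `metadata`. The JSON round-trips
#' through [jsonlite::fromJSON()].
#'
#' @param report A `calibration_report`.
#' @param path Optional file to write to.
#' @return The JSON string (invisibly when `path` is given).
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "calibration_report"))
  js <- jsonlite::toJSON(report_to_list(report), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
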