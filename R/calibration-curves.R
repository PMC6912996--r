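#' Flexible calibration curve (moderate calibration)
#'
#' Estimates the relation between predicted risk (x-axis) and observed event
#' proportion (y-axis) with a flexible smoother and a pointwise confidence
#' band. A curve close to the diagonal indicates that predicted risks
#' correspond well to observed proportions.
#'
#' Two smoothers are available:
#' \describe{
#'   \item{`spline`}{Logistic regression of the outcome on a restricted
#'     (natural) cubic spline of logit(predicted risk) with 5 knots at the
#'     0.05, 0.275, 0.5, 0.725 and 0.95 quantiles; the band maps the linear
#'     predictor's Wald interval through the inverse logit.}
#'   \item{`loess`}{Local linear regression of the outcome on the predicted
#'     risk (tricube weights over the nearest `span` fraction of subjects, no
#'     robustness iterations — they misbehave on 0/1 outcomes); the pointwise
#'     SE comes from the smoother's equivalent-kernel weights with binomial
#'     variance, and fitted values are truncated to \[0, 1\].}
#' }
#'
#' The grid covers `n_grid` equally spaced points between the 1st and 99th
#' percentiles of the predicted risks: the curve is never extrapolated beyond
#' the supported risk range.
#'
#' @param ds A [validation_dataset()] with at least 50 subjects and at least
#'   10 distinct predicted risks. Below that, moderate calibration is not
#'   reliably estimable and the error directs users to the calibration
#'   intercept and slope instead.
#' @param method `"spline"` (default) or `"loess"`.
#' @param span Loess span (fraction of subjects in each local fit).
#' @param n_grid Number of grid points.
#' @param level Confidence level of the pointwise band.
#' @return An object of class `calibration_curve`: `grid`, `fitted`,
#'   `ci_low`, `ci_high` (all in \[0, 1\]), `method`, `span_or_knots`,
#'   `n_grid`, and diagonal-deviation summaries `max_abs_dev` and
#'   `mean_abs_dev`.
#' @export
flexible_curve <- function(ds, method = c("spline", "loess"), span = 0.75,
                           n_grid = 100L, level = 0.95) {
  stopifnot(inherits(ds, "validation_dataset"))
  method <- match.arg(method)
  n_distinct <- length(unique(ds$predicted_risk))
  if (ds$n < 50 || n_distinct < 10) {
    stop("too few subjects or distinct risks for a flexible calibration curve; ",
         "in small datasets evaluate weak calibration (calibration intercept ",
         "and slope) instead", call. = FALSE)
  }
  if (n_distinct < 2) stop("curve not estimable: constant risks", call. = FALSE)
  p <- clip_risk(ds$predicted_risk)
  y <- ds$outcome
  qs <- stats::quantile(p, c(0.01, 0.99), names = FALSE)
  grid <- seq(qs[1], qs[2], length.out = n_grid)
  z <- stats::qnorm(1 - (1 - level) / 2)

  if (method == "spline") {
    lp <- logit(p)
    kq <- stats::quantile(lp, c(0.05, 0.275, 0.5, 0.725, 0.95), names = FALSE)
    if (length(unique(kq)) < 5) {
      stop("spline knot placement failed: at least 5 distinct knot quantiles ",
           "of logit(risk) are required", call. = FALSE)
    }
    basis <- splines::ns(lp, knots = kq[2:4], Boundary.knots = kq[c(1, 5)])
    fit <- stats::glm(y ~ basis, family = stats::binomial())
    newb <- splines::ns(logit(grid), knots = kq[2:4],
                        Boundary.knots = kq[c(1, 5)])
    X <- cbind(1, newb)
    eta <- drop(X %*% stats::coef(fit))
    se_eta <- sqrt(rowSums((X %*% stats::vcov(fit)) * X))
    fitted <- expit(eta)
    lo <- expit(eta - z * se_eta)
    hi <- expit(eta + z * se_eta)
    meta <- list(knots = kq)
  } else {
    sm <- local_linear_smooth(p, y, grid, span = span)
    fitted <- pmin(pmax(sm$fitted, 0), 1)
    lo <- pmin(pmax(sm$fitted - z * sm$se, 0), 1)
    hi <- pmin(pmax(sm$fitted + z * sm$se, 0), 1)
    meta <- list(span = span)
  }
  dev <- abs(fitted - grid)
  structure(
    list(grid = grid, fitted = fitted,
         ci_low = pmin(lo, fitted), ci_high = pmax(hi, fitted),
         method = method, span_or_knots = meta, n_grid = n_grid,
         level = level,
         max_abs_dev = max(dev), mean_abs_dev = mean(dev)),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Flexible calibration curve (%s), %d grid points on [%.3f, %.3f]\n",
              x$method, x$n_grid, min(x$grid), max(x$grid)))
  cat(sprintf("  deviation from diagonal: max %.4f, mean %.4f\n",
              x$max_abs_dev, x$mean_abs_dev))
  invisible(x)
}

#' Export a calibration curve as a data frame
#'
#' @param x A `calibration_curve`.
#' @param row.names,optional,... Passed through for S3 consistency; unused.
#' @return A data frame with columns `risk`, `observed`, `ci_low`, `ci_high`.
#' @export
as.data.frame.calibration_curve <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(risk = x$grid, observed = x$fitted,
             ci_low = x$ci_low, ci_high = x$ci_high)
}

#' Write a calibration curve to CSV
#'
#' @param curve A `calibration_curve`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Local linear smoother with loess-style nearest-neighbour tricube weights.
# At each grid point the nearest ceil(span * n) observations get weight
# (1 - (d/dmax)^3)^3 and a weighted straight line is fitted; the fit is a
# linear functional l(x0)' y, so its SE is sqrt(sum(l^2 * var_i)) with
# binomial variance var_i = fitted_i (1 - fitted_i) evaluated at the local fit
# (equivalent-kernel construction). stats::loess cannot return SEs at the
# cohort sizes this package simulates, hence the explicit evaluation.
local_linear_smooth <- function(x, y, grid, span = 0.75) {
  n <- length(x)
  q <- max(2L, min(n, as.integer(ceiling(span * n))))
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  fitted <- se <- numeric(length(grid))
  for (j in seq_along(grid)) {
    x0 <- grid[j]
    # window of the q nearest sorted x values (two-pointer on sorted data)
    lo <- findInterval(x0, xs)
    l <- max(1L, lo); r <- min(n, lo + 1L)
    while (r - l + 1L < q) {
      if (l == 1L) r <- r + 1L
      else if (r == n) l <- l - 1L
      else if (x0 - xs[l - 1L] <= xs[r + 1L] - x0) l <- l - 1L
      else r <- r + 1L
    }
    idx <- l:r
    d <- abs(xs[idx] - x0)
    dmax <- max(d)
    w <- if (dmax == 0) rep(1, length(d)) else (1 - pmin(d / dmax, 1)^3)^3
    u <- xs[idx] - x0
    # weighted least squares for intercept at x0: closed-form 2x2 solve
    sw <- sum(w); swu <- sum(w * u); swu2 <- sum(w * u^2)
    det <- sw * swu2 - swu^2
    if (det <= 0) {
      lvec <- w / sw
    } else {
      lvec <- (swu2 * w - swu * w * u) / det
    }
    f <- sum(lvec * ys[idx])
    fitted[j] <- f
    v <- min(max(f, 0), 1)
    se[j] <- sqrt(sum(lvec^2 * v * (1 - v)))
  }
  list(fitted = fitted, se = se)
}

#' Monte Carlo coverage of the calibration-curve confidence band
#'
#' Repeatedly simulates cohorts from a generator configuration (optionally
#' with injected miscalibration), fits the flexible curve, and records whether
#' the true calibration curve lies inside the pointwise band at the interior
#' grid point nearest the median predicted risk. Validates the band
#' construction: under a correctly specified band the coverage should match
#' `level`.
#'
#' @param config A [generator_config()].
#' @param n_reps Number of replicates (at least 100).
#' @param seed Integer seed governing all replicates.
#' @param params Optional [miscalibration_params()] applied to every cohort.
#' @param method,level Passed to [flexible_curve()].
#' @return A list: `coverage`, `mc_se` (binomial Monte Carlo SE), `n_reps`.
#' @export
curve_band_coverage <- function(config, n_reps, seed, params = NULL,
                                method = "spline", level = 0.95) {
  if (n_reps < 100) stop("too few replicates: use n_reps >= 100", call. = FALSE)
  seeds <- derive_seeds(seed, n_reps)
  hits <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- seeds[i]
    ds <- generate_binormal(cfg)
    if (!is.null(params)) ds <- inject_miscalibration(ds, params)
    cv <- flexible_curve(ds, method = method, level = level)
    j <- which.min(abs(cv$grid - stats::median(ds$predicted_risk)))
    # true observed-proportion curve at reported risk r:
    # identity when calibrated, expit(a + b logit(r)) after injection
    truth <- if (is.null(params)) cv$grid[j] else
      expit(params$a + params$b * logit(cv$grid[j]))
    hits[i] <- cv$ci_low[j] <= truth && truth <= cv$ci_high[j]
  }
  cov <- mean(hits)
  list(coverage = cov, mc_se = sqrt(cov * (1 - cov) / n_reps), n_reps = n_reps)
}
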