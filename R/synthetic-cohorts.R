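#' Generator configuration for binormal synthetic cohorts
#'
#' Describes a cohort by its size, outcome prevalence, and target
#' discrimination. Under the equal-variance binormal model a latent marker is
#' normal within each outcome class with unit variance and mean separation
#' `delta = sqrt(2) * qnorm(auc)`, which links the target c-statistic to the
#' risk distribution in closed form.
#'
#' @param n Cohort size (at least 2).
#' @param prevalence Outcome prevalence in (0, 1).
#' @param auc Target c-statistic in \[0.5, 0.999\].
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n, prevalence, auc, seed) {
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must lie in (0, 1)", call. = FALSE)
  }
  if (auc < 0.5 || auc > 0.999) {
    stop("auc must lie in [0.5, 0.999]", call. = FALSE)
  }
  structure(
    list(n = as.integer(n), prevalence = prevalence, auc = auc,
         seed = as.integer(seed),
         delta = sqrt(2) * stats::qnorm(auc)),
    class = "generator_config"
  )
}

#' Linear-logit miscalibration parameters
#'
#' Intercept `a` and slope `b` of the true recalibration map from reported
#' risks back to event probabilities: after injection,
#' `logit(P(event)) = a + b * logit(reported risk)`. Negative `a` makes the
#' reported risks overestimate; `b < 1` makes them too extreme.
#'
#' @param a Intercept distortion (log-odds).
#' @param b Slope distortion (must be positive).
#' @return An object of class `miscalibration_params`.
#' @export
miscalibration_params <- function(a, b) {
  if (b <= 0) stop("slope distortion b must be positive", call. = FALSE)
  structure(list(a = a, b = b), class = "miscalibration_params")
}

#' Generate a perfectly calibrated binormal cohort
#'
#' Draws outcomes `y ~ Bernoulli(prevalence)`, a marker
#' `x ~ Normal(delta * y, 1)`, and sets the exact posterior event probability
#' `logit(p) = logit(prevalence) + delta * x - delta^2 / 2`. The predicted
#' risk equals this true risk, so the generated model is perfectly calibrated
#' by construction and has population c-statistic equal to `auc`.
#'
#' @param config A [generator_config()].
#' @return A [validation_dataset()] with `true_risk` set (equal to
#'   `predicted_risk`).
#' @examples
#' ds <- generate_binormal(generator_config(2000, 0.25, 0.71, seed = 7))
#' mean(ds$outcome)
#' @export
generate_binormal <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  d <- config$delta
  y <- stats::rbinom(config$n, 1, config$prevalence)
  x <- stats::rnorm(config$n, mean = d * y, sd = 1)
  p <- expit(logit(config$prevalence) + d * x - d^2 / 2)
  validation_dataset(predicted_risk = p, outcome = y, true_risk = p)
}

#' Inject linear-logit miscalibration into a synthetic cohort
#'
#' Distorts the *reported* predicted risks while leaving outcomes (driven by
#' the true risks) untouched, which is the situation a model faces in a new
#' population. The reported risk satisfies
#' `logit(reported) = (logit(true) - a) / b`, so by construction the
#' recalibration model fitted to the reported risks has estimand intercept
#' `a` and slope `b`.
#'
#' @param ds A [validation_dataset()] carrying `true_risk`.
#' @param params A [miscalibration_params()].
#' @return The dataset with distorted `predicted_risk`; `true_risk` and
#'   `outcome` unchanged.
#' @export
inject_miscalibration <- function(ds, params) {
  stopifnot(inherits(ds, "validation_dataset"),
            inherits(params, "miscalibration_params"))
  if (is.null(ds$true_risk)) {
    stop("'true_risk' is missing: miscalibration can only be injected into ",
         "synthetic cohorts", call. = FALSE)
  }
  reported <- expit((logit(clip_risk(ds$true_risk, warn = FALSE)) - params$a) /
                      params$b)
  validation_dataset(predicted_risk = reported, outcome = ds$outcome,
                     true_risk = ds$true_risk, covariates = ds$covariates,
                     id = ds$id)
}

#' Miscalibration archetype presets
#'
#' Named scenarios at 25% prevalence and c-statistic 0.71: general
#' overestimation (`a = -1`) and underestimation (`a = 1`) of predicted risks
#' with slope 1, risks that are too extreme (`b = 0.6`) or not extreme enough
#' (`b = 1.6`) with intercept 0, and a combined scenario of overestimated and
#' overly extreme risks (`a = -1.04`, `b = 0.63`). The distortion magnitudes
#' are package defaults chosen to make each archetype visually and
#' statistically unmistakable at moderate sample sizes.
#'
#' @param n Cohort size used in each preset configuration.
#' @param seed Seed stored in each configuration.
#' @return A named list; each element has components `config`
#'   ([generator_config()]) and `params` ([miscalibration_params()]).
#' @export
scenario_presets <- function(n = 50000L, seed = 1L) {
  base <- function(s) generator_config(n, 0.25, 0.71, seed = s)
  list(
    overestimation  = list(config = base(seed), params = miscalibration_params(-1, 1)),
    underestimation = list(config = base(seed), params = miscalibration_params(1, 1)),
    too_extreme     = list(config = base(seed), params = miscalibration_params(0, 0.6)),
    too_moderate    = list(config = base(seed), params = miscalibration_params(0, 1.6)),
    combined        = list(config = base(seed), params = miscalibration_params(-1.04, 0.63))
  )
}

#' Generate a cohort with covariates from a logistic model
#'
#' Draws standard-normal covariates and solves the model intercept
#' numerically so that the mean event probability equals `prevalence_target`
#' (within 1e-6); outcomes are Bernoulli draws from the logistic model. Used
#' to test full refitting by coefficient recovery.
#'
#' @param n Cohort size (at least 2).
#' @param coefficients Numeric vector of covariate effects (log-odds per SD).
#' @param prevalence_target Target mean event probability in (0, 1).
#' @param seed Integer seed.
#' @return A [validation_dataset()] whose `predicted_risk` and `true_risk`
#'   are the model's probabilities and whose `covariates` matrix holds the
#'   drawn predictors.
#' @export
generate_covariate_cohort <- function(n, coefficients, prevalence_target, seed) {
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  coefficients <- as.numeric(coefficients)
  if (any(!is.finite(coefficients))) {
    stop("coefficients must be finite", call. = FALSE)
  }
  if (prevalence_target <= 0 || prevalence_target >= 1) {
    stop("prevalence target unreachable: must lie in (0, 1)", call. = FALSE)
  }
  set.seed(as.integer(seed))
  k <- length(coefficients)
  X <- matrix(stats::rnorm(n * k), nrow = n, ncol = k,
              dimnames = list(NULL, paste0("covariate_", seq_len(k))))
  eta0 <- drop(X %*% coefficients)
  f <- function(b0) mean(expit(b0 + eta0)) - prevalence_target
  b0 <- stats::uniroot(f, c(-50, 50), tol = 1e-10)$root
  p <- expit(b0 + eta0)
  y <- stats::rbinom(n, 1, p)
  validation_dataset(predicted_risk = p, outcome = y, true_risk = p,
                     covariates = X)
}

# Independent sub-seeds below 2^31 derived from one master seed.
derive_seeds <- function(seed, k) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, k)
}
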