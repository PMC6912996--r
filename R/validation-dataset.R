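#' Construct a validation dataset of predicted risks and observed outcomes
#'
#' The universal input of the package: one predicted risk in \[0, 1\] and one
#' binary outcome per subject, optionally accompanied by the true event
#' probability (synthetic cohorts only) and a numeric covariate matrix (needed
#' only for full refitting).
#'
#' @param predicted_risk Numeric vector of predicted event probabilities,
#'   each in \[0, 1\].
#' @param outcome Binary outcome per subject, coded 0/1 (logical vectors are
#'   accepted and coerced).
#' @param true_risk Optional numeric vector of true event probabilities, used
#'   by the synthetic-cohort generator so that estimators can be checked by
#'   parameter recovery.
#' @param covariates Optional numeric matrix (or data frame of numeric
#'   columns) of predictors, one row per subject; required by [refit_model()].
#' @param id Optional vector of subject labels.
#'
#' @return An object of class `validation_dataset`: a list with elements
#'   `predicted_risk`, `outcome`, `true_risk`, `covariates`, `id`, `n`,
#'   `n_events`, `n_nonevents`.
#'
#' @examples
#' ds <- validation_dataset(c(0.2, 0.4, 0.6, 0.8), c(0, 1, 1, 1))
#' ds$n_events
#' @export
validation_dataset <- function(predicted_risk, outcome, true_risk = NULL,
                               covariates = NULL, id = NULL) {
  if (length(predicted_risk) == 0L) {
    stop("no records: 'predicted_risk' is empty", call. = FALSE)
  }
  predicted_risk <- as.numeric(predicted_risk)
  if (is.logical(outcome)) outcome <- as.integer(outcome)
  outcome <- as.numeric(outcome)
  if (length(outcome) != length(predicted_risk)) {
    stop("'predicted_risk' and 'outcome' must have equal length", call. = FALSE)
  }
  if (anyNA(predicted_risk) || anyNA(outcome)) {
    stop("missing values in 'predicted_risk' or 'outcome'", call. = FALSE)
  }
  if (any(predicted_risk < 0 | predicted_risk > 1)) {
    stop("every 'predicted_risk' must lie in [0, 1]", call. = FALSE)
  }
  if (!all(outcome %in% c(0, 1))) {
    stop("every 'outcome' must be 0 or 1", call. = FALSE)
  }
  if (!is.null(true_risk)) {
    true_risk <- as.numeric(true_risk)
    if (length(true_risk) != length(predicted_risk)) {
      stop("'true_risk' must match 'predicted_risk' in length", call. = FALSE)
    }
    if (any(true_risk < 0 | true_risk > 1)) {
      stop("every 'true_risk' must lie in [0, 1]", call. = FALSE)
    }
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
    if (nrow(covariates) != length(predicted_risk)) {
      stop("'covariates' must have one row per subject", call. = FALSE)
    }
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("covariate_", seq_len(ncol(covariates)))
    }
  }
  structure(
    list(
      predicted_risk = predicted_risk,
      outcome = as.integer(outcome),
      true_risk = true_risk,
      covariates = covariates,
      id = id,
      n = length(outcome),
      n_events = sum(outcome == 1),
      n_nonevents = sum(outcome == 0)
    ),
    class = "validation_dataset"
  )
}

#' @export
print.validation_dataset <- function(x, ...) {
  cat("Validation dataset:", x$n, "subjects (",
      x$n_events, "events,", x$n_nonevents, "non-events )\n")
  cat(sprintf("  event rate %.4f, mean predicted risk %.4f\n",
              mean(x$outcome), mean(x$predicted_risk)))
  if (!is.null(x$true_risk)) cat("  true risks present (synthetic cohort)\n")
  if (!is.null(x$covariates)) {
    cat("  covariates:", paste(colnames(x$covariates), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a validation dataset from a delimited text file
#'
#' Reads a CSV/TSV file of per-subject predicted risks and outcomes. Outcome
#' coding 0/1 is enforced; character labels (e.g. "no"/"yes") can be mapped
#' via `outcome_map`.
#'
#' @param path Path to a delimited text file.
#' @param risk_col,outcome_col Column names holding the predicted risk and the
#'   outcome.
#' @param true_risk_col Optional column of true risks.
#' @param covariate_cols Optional character vector of covariate column names.
#' @param outcome_map Optional named vector mapping outcome labels to 0/1,
#'   e.g. `c(no = 0, yes = 1)`.
#' @param sep Field separator; `NULL` (default) picks "," or tab from the file
#'   extension.
#' @return A [validation_dataset()].
#' @export
read_validation_data <- function(path, risk_col = "predicted_risk",
                                 outcome_col = "outcome",
                                 true_risk_col = NULL, covariate_cols = NULL,
                                 outcome_map = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(risk_col, outcome_col, true_risk_col, covariate_cols)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("column(s) not found in ", basename(path), ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  y <- df[[outcome_col]]
  if (!is.null(outcome_map)) {
    if (!all(as.character(y) %in% names(outcome_map))) {
      stop("outcome labels outside 'outcome_map': ",
           paste(setdiff(unique(as.character(y)), names(outcome_map)),
                 collapse = ", "), call. = FALSE)
    }
    y <- unname(outcome_map[as.character(y)])
  }
  if (!all(y %in% c(0, 1))) {
    stop("outcome column must be coded 0/1 (or supply 'outcome_map')",
         call. = FALSE)
  }
  validation_dataset(
    predicted_risk = df[[risk_col]],
    outcome = y,
    true_risk = if (!is.null(true_risk_col)) df[[true_risk_col]],
    covariates = if (!is.null(covariate_cols)) df[, covariate_cols, drop = FALSE],
    id = if ("id" %in% names(df)) df[["id"]]
  )
}

#' Write a validation dataset to CSV
#'
#' Columns: `id`, `predicted_risk`, `true_risk` (if present), `outcome`, and
#' any covariates.
#'
#' @param ds A [validation_dataset()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_validation_data <- function(ds, path) {
  stopifnot(inherits(ds, "validation_dataset"))
  df <- data.frame(id = if (is.null(ds$id)) seq_len(ds$n) else ds$id,
                   predicted_risk = ds$predicted_risk)
  if (!is.null(ds$true_risk)) df$true_risk <- ds$true_risk
  df$outcome <- ds$outcome
  if (!is.null(ds$covariates)) df <- cbind(df, as.data.frame(ds$covariates))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Risks exactly 0 or 1 have no finite log-odds; clip rather than drop so every
# subject keeps contributing to the likelihood.
RISK_CLIP <- 1e-10

clip_risk <- function(p, warn = TRUE) {
  n_clip <- sum(p < RISK_CLIP | p > 1 - RISK_CLIP)
  if (n_clip > 0 && warn) {
    warning(sprintf("%d predicted risk(s) clipped to [%.0e, 1 - %.0e] before logit",
                    n_clip, RISK_CLIP, RISK_CLIP), call. = FALSE)
  }
  pmin(pmax(p, RISK_CLIP), 1 - RISK_CLIP)
}

logit <- function(p) stats::qlogis(p)
expit <- function(x) stats::plogis(x)

check_two_classes <- function(ds, what) {
  if (ds$n_events == 0 || ds$n_nonevents == 0) {
    stop(what, " requires at least one event and one non-event", call. = FALSE)
  }
}

# Degenerate after clipping: every risk at a bound while both outcome classes
# are present -> offset likelihood has no interior information.
check_not_degenerate <- function(p_clipped) {
  at_low <- all(p_clipped <= RISK_CLIP)
  at_high <- all(p_clipped >= 1 - RISK_CLIP)
  if (at_low || at_high) {
    stop("degenerate risks: all predicted risks at 0 or 1 after clipping",
         call. = FALSE)
  }
}
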