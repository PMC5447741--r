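#' Score a scale from ordinal responses
#'
#' `Z_AVERAGE` standardizes each item across respondents and averages the
#' z-scores over a respondent's non-missing items (the scoring used when
#' items mix response formats).  `SUM` adds raw codes and requires complete
#' responses (otherwise the score is missing); `MEAN` averages raw codes
#' over non-missing items.
#'
#' @param responses a [response_matrix].
#' @param items item ids to score; defaults to all.
#' @param method `"Z_AVERAGE"`, `"SUM"` or `"MEAN"`.
#' @return Object of class `scale_score`: numeric vector of per-respondent
#'   scores with attributes `method`, `items`, `missing_note`.
#' @export
score_scale <- function(responses, items = NULL,
                        method = c("Z_AVERAGE", "SUM", "MEAN")) {
  method <- match.arg(method)
  stopifnot(inherits(responses, "response_matrix"))
  items <- items %||% colnames(responses$values)
  v <- subset_items(responses, items)$values
  scores <- switch(method,
    Z_AVERAGE = {
      sds <- apply(v, 2L, stats::sd, na.rm = TRUE)
      bad <- is.na(sds) | sds == 0
      if (any(bad))
        stop("zero-variance item under Z_AVERAGE scoring: ",
             paste(colnames(v)[bad], collapse = ", "))
      z <- scale(v)
      rowMeans(z, na.rm = TRUE)
    },
    SUM = {
      out <- rowSums(v)           # NA whenever any item is missing
      out
    },
    MEAN = rowMeans(v, na.rm = TRUE)
  )
  scores[is.nan(scores)] <- NA_real_
  structure(as.numeric(scores),
            names = responses$respondent_ids,
            method = method, items = items,
            missing_note = switch(method,
              Z_AVERAGE = "averaged over non-missing items",
              SUM = "missing if any item missing",
              MEAN = "averaged over non-missing items"),
            class = "scale_score")
}

#' @export
print.scale_score <- function(x, ...) {
  cat(sprintf("%s scores for %d respondents over %d items (%s)\n",
              attr(x, "method"), length(x), length(attr(x, "items")),
              attr(x, "missing_note")))
  print(summary(as.numeric(x)))
  invisible(x)
}

#' Residualize log-BMI on demographic covariates
#'
#' Ordinary least-squares residuals of log(BMI) regressed (with intercept)
#' on age, biological sex, education, race/ethnicity and income; categorical
#' covariates enter as indicator contrasts.  The residual is the
#' demography-adjusted (log) adiposity measure used in validity
#' correlations.  Aliased (rank-deficient) design columns are dropped with
#' a warning.
#'
#' @param covariates a `covariate_table` (or data frame with a `bmi` column
#'   and any of `age`, `sex`, `education`, `race_ethnicity`, `income`).
#' @return Numeric vector of residuals (NA where BMI is missing).
#' @export
residualize_log_bmi <- function(covariates) {
  stopifnot(is.data.frame(covariates), "bmi" %in% names(covariates))
  if (any(covariates$bmi <= 0, na.rm = TRUE))
    stop("BMI must be positive")
  vars <- intersect(c("age", "sex", "education", "race_ethnicity", "income"),
                    names(covariates))
  df <- covariates[, c("bmi", vars), drop = FALSE]
  for (v in vars) if (!is.numeric(df[[v]])) df[[v]] <- factor(df[[v]])
  # constant columns carry no information; drop them silently
  keep <- vars[vapply(vars, function(v)
    length(unique(df[[v]][!is.na(df[[v]])])) > 1L, logical(1))]
  form <- if (length(keep))
    stats::as.formula(paste("log(bmi) ~", paste(keep, collapse = " + ")))
  else stats::as.formula("log(bmi) ~ 1")
  fit <- stats::lm(form, data = df, na.action = stats::na.exclude)
  if (any(is.na(stats::coef(fit))))
    warning("rank-deficient covariate design; aliased columns dropped")
  as.numeric(stats::residuals(fit))
}

#' Pearson correlation with two-sided p-value
#'
#' Pairwise-complete Pearson correlation; p from the t transform with
#' n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors.
#' @return List `r`, `p`, `n` (complete pairs used).
#' @export
correlate <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop("zero variance in x or y")
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Logistic association between a scale score and a binary outcome
#'
#' Maximum-likelihood logistic regression of the outcome on the score
#' (intercept plus slope, fitted by iteratively reweighted least squares),
#' with Wald standard error, z and p for the slope and the odds ratio
#' `OR = exp(b)`.
#'
#' @param score numeric scores.
#' @param outcome binary outcome (logical or 0/1).
#' @return List `b`, `se`, `z`, `p`, `OR`, `intercept`, `n`.
#' @export
logistic_assoc <- function(score, outcome) {
  outcome <- as.integer(outcome)
  ok <- stats::complete.cases(score, outcome)
  score <- score[ok]; outcome <- outcome[ok]
  if (length(unique(outcome)) < 2L)
    stop("both outcome classes must be present")
  fit <- stats::glm(outcome ~ score, family = stats::binomial(),
                    control = list(epsilon = 1e-10, maxit = 100L))
  mu <- stats::fitted(fit)
  if (any(mu < 1e-8 | mu > 1 - 1e-8) && abs(stats::coef(fit)[2L]) > 15)
    stop("perfect (or quasi-perfect) separation: slope diverges, |b| = ",
         round(abs(stats::coef(fit)[2L]), 1))
  sm <- summary(fit)$coefficients
  list(b = unname(sm["score", "Estimate"]),
       se = unname(sm["score", "Std. Error"]),
       z = unname(sm["score", "z value"]),
       p = unname(sm["score", "Pr(>|z|)"]),
       OR = exp(unname(sm["score", "Estimate"])),
       intercept = unname(sm["(Intercept)", "Estimate"]),
       n = length(outcome))
}

#' Validity report for a scored scale
#'
#' Convenience wrapper assembling the external-validity statistics:
#' Pearson correlations of the score with residualized log-BMI and any
#' further outcome columns, plus the logistic association with a binary
#' diagnosis.
#'
#' @param score a [scale_score] (or numeric vector).
#' @param covariates a `covariate_table` with `bmi` and `diabetes_t2`.
#' @param outcomes optional named list of additional numeric outcome
#'   vectors (e.g. craving scores).
#' @return List `bmi` (r/p/n vs residualized log-BMI), `diabetes`
#'   (logistic association), and one r/p/n entry per extra outcome.
#' @export
validity_report <- function(score, covariates, outcomes = list()) {
  res <- residualize_log_bmi(covariates)
  out <- list(bmi = correlate(as.numeric(score), res),
              diabetes = logistic_assoc(as.numeric(score),
                                        covariates$diabetes_t2))
  for (nm in names(outcomes))
    out[[nm]] <- correlate(as.numeric(score), outcomes[[nm]])
  out
}
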