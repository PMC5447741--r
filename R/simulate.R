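#' Generating models for graded ordinal responses
#'
#' A generating model is a normal-ogive graded response model with three
#' correlated latent factors (the three RRE domains).  Each item i loads on
#' the factor of its domain with loading lambda_i and has strictly increasing
#' thresholds tau_i on the underlying-variate metric.  The delta
#' parameterization is used throughout: the underlying variate has unit total
#' variance (residual variance 1 - lambda_i^2), so thresholds are directly
#' comparable across items on one probit scale.
#'
#' @param bank an [item_bank]; every item must carry one of the three
#'   substantive domains (not `OUT_OF_DOMAIN`).
#' @param loadings named numeric vector of loadings, `abs(lambda) < 1`.
#' @param thresholds named list of strictly increasing numeric vectors,
#'   item i's vector of length `n_options[i] - 1`.
#' @param factor_corr 3x3 symmetric positive-definite matrix, unit diagonal,
#'   rows/columns ordered as [red_factor_names()].
#' @param n default respondent count for [simulate_study()].
#' @return An object of class `generating_model`.
#' @export
generating_model <- function(bank, loadings, thresholds, factor_corr, n) {
  bank <- validate_item_bank(bank)
  if (any(bank$domain == "OUT_OF_DOMAIN"))
    stop("generating models need a substantive domain for every item")
  loadings <- loadings[bank$id]
  if (anyNA(loadings)) stop("loadings missing for some bank items")
  if (any(abs(loadings) >= 1))
    stop("|loading| must be < 1 (unit underlying variance); offending item: ",
         bank$id[which(abs(loadings) >= 1)[1L]])
  thresholds <- thresholds[bank$id]
  for (i in seq_len(nrow(bank))) {
    tau <- thresholds[[i]]
    if (is.null(tau) || length(tau) != bank$n_options[i] - 1L)
      stop("item ", bank$id[i], " needs ", bank$n_options[i] - 1L,
           " thresholds")
    if (any(diff(tau) <= 0))
      stop("thresholds for item ", bank$id[i], " must be strictly increasing")
  }
  check_factor_corr(factor_corr)
  structure(list(bank = bank, loadings = loadings, thresholds = thresholds,
                 factor_corr = factor_corr, n = as.integer(n)),
            class = "generating_model")
}

#' @rdname generating_model
#' @export
red_factor_names <- function() {
  c("LOSS_OF_CONTROL", "LACK_OF_SATIETY", "PREOCCUPATION")
}

check_factor_corr <- function(m) {
  if (!is.matrix(m) || nrow(m) != 3L || ncol(m) != 3L)
    stop("factor_corr must be a 3x3 matrix")
  if (max(abs(m - t(m))) > 1e-12) stop("factor_corr must be symmetric")
  if (max(abs(diag(m) - 1)) > 1e-12) stop("factor_corr must have unit diagonal")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("factor_corr is not positive definite")
  invisible(m)
}

#' @export
print.generating_model <- function(x, ...) {
  cat("Generating model:", nrow(x$bank), "items, n =", x$n, "\n")
  cat("  loadings in [", round(min(x$loadings), 2), ",",
      round(max(x$loadings), 2), "]; factor correlations",
      paste(round(x$factor_corr[lower.tri(x$factor_corr)], 2),
            collapse = ", "), "\n")
  invisible(x)
}

#' Draw latent trait values
#'
#' Respondent latent positions on the three RRE domains are drawn from a
#' trivariate normal with mean zero and covariance `factor_corr` (the
#' standard-normal latent convention).
#'
#' @param n respondent count.
#' @param factor_corr 3x3 correlation matrix (positive definite).
#' @param seed optional integer seed; when given, results are reproducible.
#' @return `n` x 3 matrix of latent values, columns [red_factor_names()].
#' @export
simulate_latent <- function(n, factor_corr = diag(3), seed = NULL) {
  check_factor_corr(factor_corr)
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(stats::rnorm(n * 3L), n, 3L)
  theta <- z %*% chol(factor_corr)
  colnames(theta) <- red_factor_names()
  theta
}

#' Simulate graded responses from a generating model
#'
#' For respondent j and item i with domain d, the underlying variate is
#' `y* = lambda_i * theta_jd + eps`, `eps ~ N(0, 1 - lambda_i^2)`; the
#' recorded response is the number of thresholds strictly below `y*`
#' (a 0-based code).  At a trait value where `lambda_i * theta` equals a
#' threshold, the probability of responding at or above that category is
#' exactly 50%.
#'
#' @param latent n x 3 matrix from [simulate_latent()].
#' @param model a [generating_model].
#' @param missing_rate optional MCAR missingness rate in `[0, 1)`, default 0.
#' @param seed optional integer seed.
#' @return A [response_matrix].
#' @export
simulate_responses <- function(latent, model, missing_rate = 0, seed = NULL) {
  stopifnot(inherits(model, "generating_model"))
  latent <- as.matrix(latent)
  if (ncol(latent) != 3L) stop("latent matrix must have 3 columns")
  stopifnot(missing_rate >= 0, missing_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  bank <- model$bank
  n <- nrow(latent)
  fcol <- match(bank$domain, red_factor_names())
  vals <- matrix(NA_integer_, n, nrow(bank), dimnames = list(NULL, bank$id))
  for (i in seq_len(nrow(bank))) {
    lam <- model$loadings[i]
    ystar <- lam * latent[, fcol[i]] +
      stats::rnorm(n, sd = sqrt(1 - lam^2))
    vals[, i] <- findInterval(ystar, model$thresholds[[i]], left.open = TRUE)
  }
  if (missing_rate > 0) {
    vals[matrix(stats::runif(length(vals)) < missing_rate,
                nrow(vals))] <- NA_integer_
  }
  response_matrix(vals, bank)
}

# ---- study presets --------------------------------------------------------

preset_bank_items <- function(kind) {
  # reference scale: 9 items spanning the three domains; loadings follow the
  # published single-factor estimates for these items, candidate loadings
  # without a published value are set mid-range.
  ref <- data.frame(
    id = paste0("red", 1:9),
    source = c("RED9", "TFEQ", "TFEQ", "RED9", "TFEQ", "RED9", "BES", "BES",
               "RED9"),
    domain = c(rep("LOSS_OF_CONTROL", 4), rep("LACK_OF_SATIETY", 2),
               rep("PREOCCUPATION", 3)),
    lambda = c(0.82, 0.81, 0.61, 0.86, 0.72, 0.59, 0.88, 0.80, 0.88),
    shift = c(0.15, 0.25, 0.05, 0.20, 0.35, 0.30, 0.45, 0.55, 0.40),
    is_reference = TRUE, stringsAsFactors = FALSE
  )
  cand <- data.frame(
    id = c("debq2", "ei1", "yfas2", "pfs3", "pfs6", "fcqt10", "yfas1",
           "tfeq7", "tfeq39"),
    source = c("DEBQ", "EI", "YFAS", "PFS", "PFS", "FCQTR", "YFAS", "TFEQ",
               "TFEQ"),
    domain = c("LOSS_OF_CONTROL", "LOSS_OF_CONTROL", "LOSS_OF_CONTROL",
               "LOSS_OF_CONTROL", "LOSS_OF_CONTROL", "PREOCCUPATION",
               "PREOCCUPATION", "LOSS_OF_CONTROL", "LACK_OF_SATIETY"),
    lambda = c(0.62, 0.64, 0.73, 0.75, 0.68, 0.83, 0.78, 0.70, 0.81),
    shift = c(-0.85, -0.70, -0.40, -0.25, -0.10, 0.05, 0.15, 0.25, 0.70),
    is_reference = FALSE, stringsAsFactors = FALSE
  )
  rbind(ref, cand)
}

# thresholds for a k-option item centered at `shift`; the layout keeps every
# category's expected endorsement above ~5% at the study sample sizes, so no
# category is so rare that its threshold is inestimable in a finite sample
preset_thresholds <- function(k, shift) {
  base <- switch(as.character(k),
                 "2" = 0,
                 "3" = c(-0.45, 0.45),
                 "4" = c(-0.65, 0, 0.65),
                 "5" = c(-0.80, -0.30, 0.30, 0.80),
                 "6" = c(-0.95, -0.45, 0, 0.45, 0.95),
                 stop("no preset threshold layout for k = ", k))
  base + shift
}

#' Study-like presets for the synthetic-data generator
#'
#' Returns an item bank plus generating model emulating the structure of the
#' scale-refinement studies: 9 reference items and 9 candidate items over
#' three correlated domains.
#'
#' * `STUDY1_LIKE`: in-person sample structure, n = 238, mixed response
#'   formats (2/3/4/5 options), factor correlations 0.72-0.92.
#' * `STUDY2_LIKE`: online sample, n = 380, uniform 6-option (0-5) format,
#'   factor correlations 0.79-0.81.
#' * `STUDY34_LIKE`: online samples, n = 346, uniform 5-option (0-4) format,
#'   factor correlations 0.75-0.81.
#'
#' @param preset preset name.
#' @param n optional override of the respondent count.
#' @param loadings,thresholds,factor_corr optional overrides, as in
#'   [generating_model()].
#' @return List with elements `bank` ([item_bank]) and `model`
#'   ([generating_model]).
#' @examples
#' p <- make_preset("STUDY34_LIKE", n = 100)
#' nrow(p$bank)   # 18 items
#' @export
make_preset <- function(preset = c("STUDY34_LIKE", "STUDY1_LIKE",
                                   "STUDY2_LIKE"),
                        n = NULL, loadings = NULL, thresholds = NULL,
                        factor_corr = NULL) {
  preset <- match.arg(preset)
  it <- preset_bank_items(preset)
  k <- switch(preset,
              STUDY1_LIKE = c(5, 2, 2, 5, 2, 5, 3, 4, 5,   # original formats
                              5, 5, 2, 5, 5, 5, 2, 4, 4),
              STUDY2_LIKE = rep(6L, 18L),
              STUDY34_LIKE = rep(5L, 18L))
  n_default <- switch(preset, STUDY1_LIKE = 238L, STUDY2_LIKE = 380L,
                      STUDY34_LIKE = 346L)
  fc <- switch(preset,
               STUDY1_LIKE = c(0.72, 0.92, 0.82),
               STUDY2_LIKE = c(0.79, 0.81, 0.80),
               STUDY34_LIKE = c(0.75, 0.81, 0.78))
  fcm <- diag(3)
  fcm[lower.tri(fcm)] <- fc
  fcm[upper.tri(fcm)] <- t(fcm)[upper.tri(fcm)]
  dimnames(fcm) <- list(red_factor_names(), red_factor_names())

  bank <- item_bank(id = it$id, source = it$source, domain = it$domain,
                    n_options = k, is_reference = it$is_reference)
  lam <- stats::setNames(it$lambda, it$id)
  tau <- stats::setNames(
    lapply(seq_along(k), function(i) preset_thresholds(k[i], it$shift[i])),
    it$id)
  if (!is.null(loadings)) lam[names(loadings)] <- loadings
  if (!is.null(thresholds)) tau[names(thresholds)] <- thresholds
  if (!is.null(factor_corr)) fcm <- factor_corr
  model <- generating_model(bank, lam, tau, fcm, n %||% n_default)
  list(bank = bank, model = model)
}

#' Simulate a full synthetic study
#'
#' Convenience wrapper: draws latent traits, generates responses and
#' covariates from one seed.
#'
#' @param preset passed to [make_preset()] (or a list as returned by it).
#' @param n respondent count override.
#' @param seed integer seed for all randomness.
#' @param missing_rate MCAR missingness rate for responses.
#' @return List with `bank`, `model`, `latent`, `responses`, `covariates`,
#'   and `trait` (the mean of the three latent columns, the scalar trait the
#'   covariate generator conditions on).
#' @export
simulate_study <- function(preset = "STUDY34_LIKE", n = NULL, seed = 1L,
                           missing_rate = 0) {
  p <- if (is.list(preset) && !is.null(preset$model)) preset else
    make_preset(preset, n = n)
  set.seed(seed)
  theta <- simulate_latent(p$model$n, p$model$factor_corr)
  resp <- simulate_responses(theta, p$model, missing_rate = missing_rate)
  trait <- rowMeans(theta)
  cov <- simulate_covariates(trait)
  list(bank = p$bank, model = p$model, latent = theta, responses = resp,
       covariates = cov, trait = trait)
}

#' Simulate respondent covariates and outcomes
#'
#' Generates demographics, BMI and a binary type-2-diabetes indicator
#' conditional on a scalar trait value per respondent.  log-BMI is linear in
#' the trait with normal noise; diabetes is Bernoulli with a logistic link
#' whose intercept solves the requested base rate at trait 0.  Demographic
#' categories are drawn from fixed marginal distributions typical of the
#' online samples the generator emulates.
#'
#' Default effect sizes: `bmi_slope = 0.07` with `bmi_noise_sd = 0.25`
#' implies a trait/BMI correlation near 0.27 at unit trait variance, and
#' `diabetes_logit_slope = 0.6` with a 5.5% base rate implies a modest
#' positive odds ratio per trait unit.
#'
#' @param trait numeric vector of latent trait values (finite).
#' @param bmi_intercept mean log-BMI at trait 0 (log kg/m^2).
#' @param bmi_slope log-BMI units per trait unit.
#' @param bmi_noise_sd residual SD of log-BMI (must be >= 0).
#' @param diabetes_base_rate P(diabetes) at trait 0.
#' @param diabetes_logit_slope log-odds of diabetes per trait unit.
#' @param seed optional integer seed.
#' @return A data frame of class `covariate_table` with columns `age`, `sex`,
#'   `education`, `race_ethnicity`, `income`, `bmi`, `diabetes_t2`.
#' @export
simulate_covariates <- function(trait, bmi_intercept = log(25.6),
                                bmi_slope = 0.07, bmi_noise_sd = 0.25,
                                diabetes_base_rate = 0.055,
                                diabetes_logit_slope = 0.6, seed = NULL) {
  if (any(!is.finite(trait))) stop("trait values must be finite")
  if (bmi_noise_sd < 0) stop("bmi_noise_sd must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  n <- length(trait)
  log_bmi <- bmi_intercept + bmi_slope * trait +
    stats::rnorm(n, sd = bmi_noise_sd)
  alpha <- stats::qlogis(diabetes_base_rate)
  p_dia <- stats::plogis(alpha + diabetes_logit_slope * trait)
  age <- pmin(pmax(round(stats::rnorm(n, 35, 11)), 18), 80)
  out <- data.frame(
    age = age,
    sex = sample(c("female", "male"), n, TRUE, prob = c(0.48, 0.52)),
    education = sample(c("high_school", "some_college", "associates",
                         "bachelors", "advanced"), n, TRUE,
                       prob = c(0.13, 0.29, 0.10, 0.39, 0.09)),
    race_ethnicity = sample(c("white", "black", "asian_pi", "hispanic",
                              "other"), n, TRUE,
                            prob = c(0.70, 0.08, 0.12, 0.07, 0.03)),
    income = sample(paste0("band", 1:5), n, TRUE,
                    prob = c(0.15, 0.25, 0.30, 0.20, 0.10)),
    bmi = exp(log_bmi),
    diabetes_t2 = stats::rbinom(n, 1L, p_dia) == 1L,
    stringsAsFactors = FALSE
  )
  class(out) <- c("covariate_table", "data.frame")
  out
}

#' Write a simulated study to disk
#'
#' Writes `responses.csv`, `covariates.csv`, `bank.json` and `truth.json`
#' (the generating parameters, for recovery tests) to a directory.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_responses(study$responses, file.path(dir, "responses.csv"))
  utils::write.csv(study$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  write_item_bank(study$bank, file.path(dir, "bank.json"))
  truth <- list(
    loadings = as.list(study$model$loadings),
    thresholds = study$model$thresholds,
    factor_corr = study$model$factor_corr,
    n = study$model$n,
    latent_distribution = "standard normal, correlated factors"
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
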