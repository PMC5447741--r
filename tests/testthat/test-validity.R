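small_rm <- function(vals, k = 5L) {
  bank <- item_bank(colnames(vals), domain = "PREOCCUPATION", n_options = k)
  response_matrix(vals, bank)
}

test_that("sum, mean and z-average scoring behave as defined", {
  vals <- matrix(c(0L, 1L, 2L,
                   1L, 3L, 4L,
                   2L, 0L, 1L), 3, 3, byrow = TRUE,
                 dimnames = list(NULL, c("a", "b", "c")))
  rm <- small_rm(vals)
  expect_equal(as.numeric(score_scale(rm, method = "SUM"))[1], 3)
  expect_equal(as.numeric(score_scale(rm, method = "MEAN"))[1], 1)

  z <- score_scale(rm, method = "Z_AVERAGE")
  expect_lt(abs(mean(as.numeric(z))), 1e-12)

  # SUM requires completeness
  vals[2, 3] <- NA
  s <- score_scale(small_rm(vals), method = "SUM")
  expect_true(is.na(as.numeric(s)[2]))
  expect_false(anyNA(as.numeric(s)[-2]))
})

test_that("z-average scores are invariant to affine recoding of one item", {
  set.seed(501)
  vals <- matrix(sample(0:4, 300, TRUE), 100, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  z1 <- as.numeric(score_scale(small_rm(vals), method = "Z_AVERAGE"))
  vals2 <- vals
  vals2[, 2] <- vals2[, 2] * 2L + 1L    # affine transform of item b's codes
  bank2 <- item_bank(colnames(vals2), domain = "PREOCCUPATION",
                     n_options = c(5L, 10L, 5L))
  z2 <- as.numeric(score_scale(response_matrix(vals2, bank2),
                               method = "Z_AVERAGE"))
  expect_equal(z1, z2, tolerance = 1e-12)
})

test_that("zero-variance items are refused under z-average scoring", {
  vals <- matrix(c(2L, 2L, 2L, 0L, 1L, 2L), 3, 2,
                 dimnames = list(NULL, c("flat", "ok")))
  expect_error(score_scale(small_rm(vals), method = "Z_AVERAGE"), "flat")
})

test_that("sum and z-average agree in rank with common format and no missingness", {
  set.seed(502)
  st <- simulate_study("STUDY34_LIKE", n = 150, seed = 502)
  s_sum <- as.numeric(score_scale(st$responses, method = "SUM"))
  s_z <- as.numeric(score_scale(st$responses, method = "Z_AVERAGE"))
  expect_gt(cor(s_sum, s_z, method = "spearman"), 0.99)
})

test_that("log-BMI residualization is orthogonal to its design", {
  set.seed(503)
  trait <- rnorm(400)
  cov <- simulate_covariates(trait, seed = 503)
  res <- residualize_log_bmi(cov)
  X <- model.matrix(~ age + factor(sex) + factor(education) +
                      factor(race_ethnicity) + factor(income), cov)
  expect_lt(max(abs(crossprod(X, res))), 1e-8)

  # constant covariates: residual reduces to centered log BMI
  cov2 <- cov
  cov2[c("age", "sex", "education", "race_ethnicity", "income")] <-
    list(30, "f", "hs", "w", "b1")
  res2 <- residualize_log_bmi(cov2)
  expect_equal(res2, log(cov2$bmi) - mean(log(cov2$bmi)), tolerance = 1e-12)

  expect_error(residualize_log_bmi(data.frame(bmi = c(20, -3))), "positive")
})

test_that("residuals of a constructed age effect are uncorrelated with age", {
  set.seed(504)
  n <- 1e4
  age <- round(runif(n, 20, 70))
  bmi <- exp(2.8 + 0.004 * age + rnorm(n, sd = 0.15))
  cov <- data.frame(age = age, sex = sample(c("f", "m"), n, TRUE), bmi = bmi)
  res <- residualize_log_bmi(cov)
  expect_lt(abs(cor(res, age)), 0.02)
})

test_that("pearson correlation matches hand computation and limits", {
  expect_equal(correlate(1:10, 1:10)$r, 1)
  expect_equal(correlate(1:10, -2 * (1:10) + 7)$r, -1)
  h <- correlate(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(h$r, 0.8, tolerance = 1e-12)
  expect_equal(h$n, 4L)
  expect_error(correlate(1:5, rep(1, 5)), "zero variance")
  expect_error(correlate(c(1, 2, NA), c(1, NA, 3)), "complete pairs")
})

test_that("logistic association reproduces the closed-form 2x2 odds ratio", {
  score <- rep(c(0, 1), times = c(20, 25))
  outcome <- c(rep(0, 10), rep(1, 10), rep(0, 5), rep(1, 20))
  fit <- logistic_assoc(score, outcome)
  expect_equal(fit$OR, 4, tolerance = 1e-6)
  expect_equal(fit$b, log(4), tolerance = 1e-6)
  expect_true(fit$se > 0 && is.finite(fit$z) && fit$p < 1)
})

test_that("logistic association is null when outcome ignores the score", {
  set.seed(505)
  score <- rnorm(1e4)
  outcome <- rbinom(1e4, 1, 0.5)
  fit <- logistic_assoc(score, outcome)
  expect_true(fit$OR > 0.95 && fit$OR < 1.05)
  expect_error(logistic_assoc(score, rep(1, 1e4)), "both outcome classes")
})

test_that("perfect separation is diagnosed rather than reported", {
  score <- c(rnorm(50, -3), rnorm(50, 3))
  outcome <- rep(c(0, 1), each = 50)
  expect_error(suppressWarnings(logistic_assoc(score, outcome)),
               "separation")
})

test_that("a positive trait-BMI slope yields a detectable validity correlation", {
  # 100 replicate synthetic studies at the target sample size
  hits <- 0L
  for (s in 1:100) {
    set.seed(600 + s)
    trait <- rnorm(346)
    cov <- simulate_covariates(trait)
    r <- correlate(trait, residualize_log_bmi(cov))
    hits <- hits + (r$r > 0 && r$p < 0.05)
  }
  expect_gte(hits, 95L)
})

test_that("validity reports assemble correlations and the logistic fit", {
  set.seed(507)
  trait <- rnorm(500)
  cov <- simulate_covariates(trait, seed = 507)
  vr <- validity_report(trait, cov,
                        outcomes = list(sweet = trait * 0.3 + rnorm(500)))
  expect_named(vr, c("bmi", "diabetes", "sweet"))
  expect_gt(vr$bmi$r, 0)
  expect_equal(vr$diabetes$OR, exp(vr$diabetes$b), tolerance = 1e-12)
  expect_gt(vr$sweet$r, 0)
})
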