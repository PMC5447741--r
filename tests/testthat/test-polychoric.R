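test_that("thresholds are normal quantiles of the cumulative margins", {
  expect_equal(as.numeric(estimate_thresholds(c(50, 50))), 0)
  expect_equal(as.numeric(estimate_thresholds(c(20, 20, 20, 20, 20))),
               qnorm(c(0.2, 0.4, 0.6, 0.8)), tolerance = 1e-12)
  expect_error(estimate_thresholds(c(100, 0)), "one category")
  expect_error(estimate_thresholds(c(0, 0, 7)), "one category")
  expect_error(estimate_thresholds(c(-1, 5)), "nonnegative")
})

test_that("zero-count categories collapse into their lower neighbor", {
  expect_warning(tau <- estimate_thresholds(c(30, 0, 30, 40)), "collapsed")
  expect_equal(as.numeric(tau), qnorm(c(0.3, 0.6)), tolerance = 1e-12)
  expect_equal(unname(attr(tau, "mapping")), c(0L, 0L, 1L, 2L))
  # leading zero merges upward
  expect_warning(tau2 <- estimate_thresholds(c(0, 50, 50)), "collapsed")
  expect_equal(unname(attr(tau2, "mapping")), c(0L, 0L, 1L))
})

test_that("symmetric 2x2 table recovers the closed-form quadrant solution", {
  tab <- matrix(c(40, 10, 10, 40), 2)
  rho <- polychoric_pair(tab)
  # quadrant identity: P(both high) = 1/4 + asin(rho) / (2 pi) = 0.40
  expect_equal(as.numeric(rho), sin(0.3 * pi), tolerance = 1e-4)
})

test_that("independent and transposed tables behave as expected", {
  marg <- c(30, 50, 20)
  tab <- outer(marg, c(40, 60)) / 100
  expect_lt(abs(as.numeric(polychoric_pair(tab))), 1e-4)

  set.seed(55)
  tab2 <- matrix(rpois(12, 20) + 1, 3, 4)
  expect_equal(as.numeric(polychoric_pair(tab2)),
               as.numeric(polychoric_pair(t(tab2))), tolerance = 1e-5)
})

test_that("two-step ML matches the exhaustive grid-search oracle", {
  tables <- list(
    matrix(c(40, 10, 10, 40), 2),
    matrix(c(55, 15, 8, 22), 2),
    matrix(c(30, 12, 4, 10, 25, 11, 3, 9, 26), 3),
    matrix(c(18, 9, 3, 1, 7, 14, 8, 3, 2, 8, 13, 7, 1, 3, 8, 15), 4)
  )
  for (tab in tables) {
    expect_equal(as.numeric(polychoric_pair(tab)),
                 grid_ml_polychoric(tab), tolerance = 1e-3)
  }
})

test_that("all-mass-in-one-cell tables clamp with a warning", {
  tab <- matrix(c(50, 0, 0, 0), 2)
  # single nonzero margin row/column: degenerate margins
  expect_error(polychoric_pair(tab), "one category")
  tab2 <- matrix(c(50, 0, 0, 0, 50, 0, 0, 0, 50), 3)
  expect_warning(r <- polychoric_pair(tab2, tau1 = qnorm(c(1, 2) / 3),
                                      tau2 = qnorm(c(1, 2) / 3)), NA)
  expect_gt(as.numeric(r), 0.9)
})

test_that("polychoric matrices use pairwise deletion and smooth when needed", {
  st <- simulate_study("STUDY34_LIKE", n = 400, seed = 61)
  poly <- polychoric_matrix(st$responses)
  expect_s3_class(poly, "red_poly")
  expect_true(all(poly$pairwise_n[upper.tri(poly$pairwise_n)] == 400))
  expect_true(isSymmetric(poly$corr))
  expect_true(all(abs(poly$corr) <= 1))
  expect_true(all(diag(poly$corr) == 1))

  # duplicated column: perfect agreement flags near-singularity; the
  # assembled matrix stays positive definite
  v <- st$responses$values[, 1:3]
  v[, 3] <- v[, 1]
  bank3 <- item_bank(id = c("a", "b", "adup"), n_options = 5L,
                     domain = "PREOCCUPATION")
  colnames(v) <- bank3$id
  poly_dup <- suppressWarnings(polychoric_matrix(response_matrix(v, bank3)))
  expect_true(any(poly_dup$near_singular))
  expect_gte(max(poly_dup$corr[upper.tri(poly_dup$corr)]), 1 - 1e-4)
  ev <- eigen(poly_dup$corr, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("indefinite pairwise-deletion matrices are smoothed to PSD", {
  # three binary items observed pairwise in disjoint subsamples, with
  # correlations (+, +, -) that no trivariate normal can produce
  set.seed(63)
  n_blk <- 120L
  mk_pair <- function(rho) {
    z <- matrix(rnorm(n_blk * 2), ncol = 2)
    z[, 2] <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
    cbind(as.integer(z[, 1] > 0), as.integer(z[, 2] > 0))
  }
  v <- matrix(NA_integer_, 3L * n_blk, 3L,
              dimnames = list(NULL, c("a", "b", "c")))
  v[1:n_blk, c(1, 2)] <- mk_pair(0.95)
  v[(n_blk + 1):(2 * n_blk), c(1, 3)] <- mk_pair(0.95)
  v[(2 * n_blk + 1):(3 * n_blk), c(2, 3)] <- mk_pair(-0.95)
  bank <- item_bank(id = c("a", "b", "c"), n_options = 2L,
                    domain = "PREOCCUPATION")
  poly <- suppressWarnings(polychoric_matrix(response_matrix(v, bank)))
  expect_true(poly$smoothed)
  ev <- eigen(poly$corr, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0)
  expect_equal(unname(diag(poly$corr)), rep(1, 3))
})

test_that("item pairs with too few complete observations are refused", {
  bank <- item_bank(id = c("a", "b"), n_options = 2L)
  v <- matrix(NA_integer_, 30, 2, dimnames = list(NULL, c("a", "b")))
  v[1:15, 1] <- rep(0:1, length.out = 15)
  v[12:30, 2] <- rep(0:1, length.out = 19)   # only 4 complete pairs
  expect_error(polychoric_matrix(response_matrix(v, bank)),
               "'a' and 'b' share only 4 complete pairs")
})

test_that("polychorics recover the model-implied correlations lambda_i lambda_j psi", {
  st <- simulate_study("STUDY34_LIKE", n = 5000, seed = 62)
  sub_ids <- c("red1", "red4", "red5", "red7", "yfas2", "fcqt10")
  poly <- polychoric_matrix(subset_items(st$responses, sub_ids))
  lam <- st$model$loadings[sub_ids]
  dom <- st$bank$domain[match(sub_ids, st$bank$id)]
  fidx <- match(dom, red_factor_names())
  implied <- outer(lam, lam) * st$model$factor_corr[fidx, fidx]
  diag(implied) <- 1
  expect_lt(max(abs(poly$corr - implied)), 0.05)
})
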