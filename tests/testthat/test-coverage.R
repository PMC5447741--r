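test_that("logit gaps convert to normal units by the 1.7 constant", {
  expect_equal(logit_to_normal(0.5, 1.7), 0.5 / 1.7, tolerance = 1e-15)
  expect_equal(round(logit_to_normal(0.5), 2), 0.29)
  expect_equal(logit_to_normal(0), 0)
  expect_equal(logit_to_normal(1.7), 1)
  expect_error(logit_to_normal(0.5, 0), "positive")
})

test_that("the gap criterion carries full precision, not the rounded 0.29", {
  crit <- gap_criterion()
  expect_equal(crit$normal_gap, 0.5 / 1.7, tolerance = 1e-15)
  expect_equal(crit$half_window, 0.25 / 1.7, tolerance = 1e-15)
  expect_error(gap_criterion(trait_range = c(2, -2)))
})

test_that("interior and edge gaps follow the half-window construction", {
  crit <- gap_criterion(trait_range = c(-1, 0.5))
  gaps <- find_gaps(c(-1, 0, 0.5), crit)
  hw <- crit$half_window
  expect_equal(nrow(gaps), 2L)
  expect_equal(gaps$lower, c(-1 + hw, 0 + hw), tolerance = 1e-12)
  expect_equal(gaps$upper, c(0 - hw, 0.5 - hw), tolerance = 1e-12)
  expect_true(all(gaps$type == "interior"))
  # the construction lands on the reported approximate bounds
  expect_lt(max(abs(gaps$lower - c(-0.855, 0.145))), 0.005)
  expect_lt(max(abs(gaps$upper - c(-0.145, 0.355))), 0.005)
})

test_that("spacing at or under the criterion leaves no interior gap", {
  th <- seq(-1, 1, by = 0.2)
  gaps <- find_gaps(th, gap_criterion(trait_range = c(-1, 1)))
  expect_equal(nrow(gaps), 0L)
  # dense thresholds over the whole range: empty gap set
  th2 <- seq(-2, 2, by = 0.25)
  gaps2 <- find_gaps(th2, gap_criterion(trait_range = range(th2)))
  expect_equal(nrow(gaps2), 0L)
  expect_error(find_gaps(numeric(0), gap_criterion()), "empty")
})

test_that("edge gaps appear when the range extends past the outer thresholds", {
  crit <- gap_criterion(trait_range = c(-3, 3))
  hw <- crit$half_window
  # 0.4 spacing also exceeds the criterion, so an interior gap sits between
  gaps <- find_gaps(c(-0.2, 0.2), crit)
  expect_identical(gaps$type, c("edge_low", "interior", "edge_high"))
  expect_equal(gaps$lower, c(-3, -0.2 + hw, 0.2 + hw), tolerance = 1e-12)
  expect_equal(gaps$upper, c(-0.2 - hw, 0.2 - hw, 3), tolerance = 1e-12)
  # tight spacing drops the interior gap, edges remain
  g2 <- find_gaps(c(-0.1, 0.1), crit)
  expect_identical(g2$type, c("edge_low", "edge_high"))
})

test_that("no gap point ever comes within half a window of a reference threshold", {
  set.seed(404)
  crit0 <- gap_criterion()
  for (rep in 1:25) {
    th <- sort(runif(sample(3:12, 1), -2.5, 2.5))
    crit <- gap_criterion(trait_range = range(th) + c(-0.8, 0.8))
    gaps <- find_gaps(th, crit)
    if (!nrow(gaps)) next
    for (g in seq_len(nrow(gaps))) {
      expect_gte(min(abs(outer(c(gaps$lower[g], gaps$upper[g]), th, "-"))),
                 crit$half_window - 1e-12)
      expect_false(any(th > gaps$lower[g] & th < gaps$upper[g]))
    }
  }
})

test_that("gap detection is translation-equivariant", {
  set.seed(405)
  th <- sort(runif(8, -2, 2))
  for (shift in c(-1.3, 0.7, 2.25)) {
    g0 <- find_gaps(th, gap_criterion(trait_range = c(-3, 3)))
    g1 <- find_gaps(th + shift,
                    gap_criterion(trait_range = c(-3, 3) + shift))
    expect_equal(g1$lower, g0$lower + shift, tolerance = 1e-12)
    expect_equal(g1$upper, g0$upper + shift, tolerance = 1e-12)
  }
})

test_that("coverage audit uses closed-interval containment", {
  gaps <- find_gaps(c(-1, 0, 1.5),
                    gap_criterion(trait_range = c(-1, 1.5)))  # 2 interior
  hw <- attr(gaps, "criterion")$half_window
  mk_map <- function(th_list) {
    ids <- names(th_list)
    structure(list(
      items = data.frame(id = ids, source = "OTHER", domain = "PREOCCUPATION",
                         is_reference = FALSE,
                         mean_threshold = vapply(th_list, mean, numeric(1)),
                         stringsAsFactors = FALSE),
      thresholds = th_list, persons = numeric(0)), class = "threshold_map")
  }
  mid1 <- mean(c(gaps$lower[1], gaps$upper[1]))
  aud <- audit_coverage(mk_map(list(
    inmid = mid1,                       # midpoint of gap 1
    boundary = gaps$lower[2],           # exactly on a gap endpoint
    outside = -1                        # on a reference threshold
  )), gaps)
  expect_identical(aud$gaps_covered[[1]], 1L)
  expect_identical(aud$gaps_covered[[2]], 2L)   # closed interval: covers
  expect_identical(aud$gaps_covered[[3]], integer(0))
  expect_identical(aud$retained, c(TRUE, TRUE, FALSE))

  both <- audit_coverage(mk_map(list(two = c(mid1, gaps$lower[2] + 1e-6))),
                         gaps)
  expect_identical(both$gaps_covered[[1]], c(1L, 2L))
})

test_that("greedy domain-balanced selection matches the exhaustive cover oracle", {
  for (fx in selection_fixtures()) {
    sel <- select_items(as_audit(fx), fx$n_gaps, fx$reference_domains)
    oracle <- exhaustive_min_covers(fx$gaps_covered)
    expect_equal(length(sel$selected), length(oracle[[1]]))
    expect_true(any(vapply(oracle, function(s)
      setequal(s, sel$selected), logical(1))))
    # every coverable gap covered
    coverable <- sort(unique(unlist(fx$gaps_covered)))
    expect_true(all(sel$gap_status$covered[coverable]))
  }
})

test_that("selection tie-breaks are deterministic and documented", {
  fx <- selection_fixtures()$identical_twins
  sel <- select_items(as_audit(fx), fx$n_gaps, fx$reference_domains)
  expect_identical(sel$selected, "A")   # lexicographic id

  fxd <- selection_fixtures()$domain_balance
  seld <- select_items(as_audit(fxd), fxd$n_gaps, fxd$reference_domains)
  # gap 1 claimed by the least represented domain (satiety), gap 2 by po1
  expect_setequal(seld$selected, c("sat1", "po1"))

  fxu <- selection_fixtures()$uncoverable_gap
  selu <- select_items(as_audit(fxu), fxu$n_gaps, fxu$reference_domains)
  expect_identical(selu$uncovered, 3L)

  # empty candidate set: all gaps flagged uncovered, no error
  empty <- data.frame(id = character(0), domain = character(0),
                      mean_threshold = numeric(0))
  empty$gaps_covered <- list()
  sel0 <- select_items(empty, 2L, character(0))
  expect_length(sel0$selected, 0L)
  expect_identical(sel0$uncovered, 1:2)
})

test_that("the published four-item extension falls out of the greedy policy", {
  ex <- refinement_example()
  sel <- select_items(ex$audit, ex$n_gaps, ex$reference_domains)
  expect_setequal(sel$selected, c("yfas2", "tfeq39", "fcqt10", "debq2"))
  expect_equal(length(sel$selected) + length(ex$reference_domains), 13L)
  # force-hooks can still pin a composition
  sel2 <- select_items(ex$audit, ex$n_gaps, ex$reference_domains,
                       force_include = "yfas1", force_exclude = "fcqt10")
  expect_true("yfas1" %in% sel2$selected)
  expect_false("fcqt10" %in% sel2$selected)
})

test_that("rater kappa matches hand computation and edge behavior", {
  # 3 raters, perfect agreement on 47 items across 4 categories
  ratings <- matrix(rep(rep(c("LOC", "SAT", "PO", "OUT"),
                            times = c(20, 10, 10, 7)), 3), ncol = 3)
  expect_equal(rater_kappa(ratings), 1)

  # hand-built 6-item, 3-rater table: direct Fleiss computation
  tab <- rbind(c("a", "a", "a"), c("a", "a", "b"), c("b", "b", "b"),
               c("b", "a", "b"), c("a", "b", "b"), c("a", "a", "a"))
  nij <- t(apply(tab, 1, function(r) c(sum(r == "a"), sum(r == "b"))))
  Pi <- (rowSums(nij^2) - 3) / (3 * 2)
  Pe <- sum((colSums(nij) / 18)^2)
  expect_equal(rater_kappa(tab), (mean(Pi) - Pe) / (1 - Pe),
               tolerance = 1e-12)

  # two independent raters: kappa near zero
  set.seed(406)
  r2 <- cbind(sample(letters[1:4], 1e4, TRUE),
              sample(letters[1:4], 1e4, TRUE))
  expect_lt(abs(rater_kappa(r2)), 0.03)
  expect_equal(rater_kappa(r2, method = "cohen"),
               rater_kappa(r2), tolerance = 1e-12)

  # mean pairwise Cohen is available as the multi-rater alternative
  expect_true(is.finite(rater_kappa(tab, method = "mean_pairwise")))

  expect_error(rater_kappa(matrix("a", 5, 3)), "single category")
  expect_error(rater_kappa(matrix("a", 5, 1)), "2 raters")
})
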