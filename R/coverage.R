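#' Convert a logit-metric gap to normal units
#'
#' Normal-ogive item response models are scaled from logistic ones by the
#' constant 1.7, so a gap expressed in logit units divides by 1.7 to land on
#' the normal (probit) metric.  The clinically motivated 0.5-logit gap
#' becomes 0.5 / 1.7 = 0.294 normal units (reported rounded as 0.29); the
#' full-precision value is carried through all computations.
#'
#' @param gap_logit gap width in logit units.
#' @param constant logistic-to-normal scaling constant (> 0).
#' @return Gap width in normal units.
#' @examples
#' logit_to_normal(0.5)       # 0.294..., the 0.29 criterion
#' @export
logit_to_normal <- function(gap_logit, constant = 1.7) {
  if (constant <= 0) stop("scaling constant must be positive")
  gap_logit / constant
}

#' The coverage-gap criterion
#'
#' A region of the latent trait counts as a coverage gap when it is farther
#' than half the criterion width from every reference-scale threshold.  The
#' default criterion is the 0.5-logit clinical-significance gap converted to
#' normal units (0.5 / 1.7), giving a half-window of 0.147 normal units.
#'
#' @param logit_gap gap criterion in logit units.
#' @param scale_constant logistic-to-normal constant.
#' @param trait_range length-2 numeric, the analyzed span of the latent
#'   trait (typically the person-location range padded by 0.25).
#' @return An object of class `gap_criterion` with fields `logit_gap`,
#'   `scale_constant`, `normal_gap`, `half_window`, `trait_range`.
#' @export
gap_criterion <- function(logit_gap = 0.5, scale_constant = 1.7,
                          trait_range = c(-3, 3)) {
  normal_gap <- logit_to_normal(logit_gap, scale_constant)
  stopifnot(length(trait_range) == 2L, trait_range[1L] < trait_range[2L])
  structure(list(logit_gap = logit_gap, scale_constant = scale_constant,
                 normal_gap = normal_gap, half_window = normal_gap / 2,
                 trait_range = as.numeric(trait_range)),
            class = "gap_criterion")
}

#' Threshold (person-item) map
#'
#' Collects per-item severities and person locations on one latent metric:
#' each item's ordered thresholds, its mean threshold (severity), source,
#' domain and reference flag, plus the EAP person locations.  By default the
#' raw underlying-variate thresholds are mapped; `irt_scale = TRUE` divides
#' each item's thresholds by its loading (2-parameter IRT-style locations).
#'
#' @param fit a `red_cfa`.
#' @param persons optional numeric person locations; computed by
#'   [estimate_person_locations()] when omitted and responses are available.
#' @param irt_scale map thresholds as `tau / lambda` instead of raw `tau`.
#' @return An object of class `threshold_map`: list with `items` (data
#'   frame: id, source, domain, is_reference, mean_threshold), `thresholds`
#'   (named list), `persons`.
#' @export
threshold_map <- function(fit, persons = NULL, irt_scale = FALSE) {
  stopifnot(inherits(fit, "red_cfa"))
  bank <- fit$responses$bank
  ids <- names(fit$loadings)
  th <- fit$poly$thresholds[ids]
  if (irt_scale) {
    th <- lapply(ids, function(i) {
      lam <- fit$loadings[[i]]
      if (abs(lam) < 1e-8) stop("cannot rescale thresholds of item ", i,
                                " with near-zero loading")
      fit$poly$thresholds[[i]] / lam
    })
    names(th) <- ids
  }
  if (is.null(persons) && !is.null(fit$responses))
    persons <- as.numeric(estimate_person_locations(fit))
  info <- if (!is.null(bank)) bank[match(ids, bank$id), , drop = FALSE] else
    data.frame(id = ids, source = "OTHER", domain = "OUT_OF_DOMAIN",
               is_reference = FALSE)
  items <- data.frame(
    id = ids,
    source = info$source,
    domain = info$domain,
    is_reference = info$is_reference,
    mean_threshold = vapply(th, mean, numeric(1)),
    stringsAsFactors = FALSE
  )
  structure(list(items = items, thresholds = th,
                 persons = persons %||% numeric(0)),
            class = "threshold_map")
}

#' @export
print.threshold_map <- function(x, ...) {
  cat("Threshold map:", nrow(x$items), "items (",
      sum(x$items$is_reference), "reference ),",
      length(x$persons), "person locations\n")
  invisible(x)
}

#' Default trait range for gap analysis
#'
#' The analyzed span of the latent continuum: the person-location range
#' padded by 0.25 on each side (the maps are bounded by the participant
#' histogram).
#'
#' @param map a [threshold_map] with person locations.
#' @param pad padding in normal units.
#' @return Length-2 numeric range.
#' @export
default_trait_range <- function(map, pad = 0.25) {
  stopifnot(inherits(map, "threshold_map"))
  if (!length(map$persons)) stop("map has no person locations")
  range(map$persons) + c(-pad, pad)
}

#' Detect coverage gaps between reference thresholds
#'
#' A gap is any part of the trait range farther than `half_window` from
#' every reference threshold.  Between each consecutive threshold pair
#' `(t_a, t_b)` with `t_b - t_a > normal_gap` the interval
#' `(t_a + half_window, t_b - half_window)` is emitted; at the edges, the
#' regions below `t_min - half_window` and above `t_max + half_window`
#' (clipped to the trait range) are emitted when nonempty.
#'
#' @param reference_thresholds numeric vector of reference-scale thresholds
#'   (any order; sorted internally).
#' @param criterion a [gap_criterion].
#' @return An object of class `gap_set`: data frame with columns `lower`,
#'   `upper`, `width`, `type` (`"edge_low"`, `"interior"`, `"edge_high"`),
#'   sorted and disjoint; the criterion is kept as attribute `"criterion"`.
#' @examples
#' crit <- gap_criterion(trait_range = c(-1, 0.5))
#' find_gaps(c(-1, 0, 0.5), crit)
#' @export
find_gaps <- function(reference_thresholds, criterion = gap_criterion()) {
  stopifnot(inherits(criterion, "gap_criterion"))
  th <- sort(as.numeric(reference_thresholds))
  if (!length(th)) stop("empty reference threshold set")
  hw <- criterion$half_window
  rng <- criterion$trait_range
  gaps <- list()
  if (rng[1L] < th[1L] - hw)
    gaps[[length(gaps) + 1L]] <- c(rng[1L], th[1L] - hw, NA)
  if (length(th) > 1L) {
    for (q in seq_len(length(th) - 1L)) {
      if (th[q + 1L] - th[q] > criterion$normal_gap)
        gaps[[length(gaps) + 1L]] <- c(th[q] + hw, th[q + 1L] - hw, q)
    }
  }
  if (rng[2L] > th[length(th)] + hw)
    gaps[[length(gaps) + 1L]] <- c(th[length(th)] + hw, rng[2L], NA)
  if (length(gaps)) {
    m <- do.call(rbind, gaps)
    out <- data.frame(lower = m[, 1L], upper = m[, 2L],
                      width = m[, 2L] - m[, 1L],
                      type = ifelse(is.na(m[, 3L]),
                                    ifelse(m[, 1L] < th[1L], "edge_low",
                                           "edge_high"),
                                    "interior"),
                      stringsAsFactors = FALSE)
    out <- out[out$width > 0, , drop = FALSE]
    out <- out[order(out$lower), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- data.frame(lower = numeric(0), upper = numeric(0),
                      width = numeric(0), type = character(0),
                      stringsAsFactors = FALSE)
  }
  structure(out, criterion = criterion, class = c("gap_set", "data.frame"))
}

#' @export
print.gap_set <- function(x, ...) {
  cat("Gap set:", nrow(x), "interval(s), total width",
      round(sum(x$width), 3), "normal units\n")
  if (nrow(x)) print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Total uncovered length of a gap set
#' @param gaps a `gap_set`.
#' @return Sum of interval widths (normal units).
#' @export
gap_length <- function(gaps) sum(gaps$width)

#' Audit which candidates cover which gaps
#'
#' A candidate covers a gap when at least one of its thresholds lies inside
#' the gap's closed interval.  Candidates covering at least one gap are
#' flagged as retained for coverage.
#'
#' @param candidates a [threshold_map] of candidate items (reference items
#'   present in the map are ignored).
#' @param gaps a `gap_set` on the same latent metric.
#' @return An object of class `coverage_audit`: data frame with columns
#'   `id`, `domain`, `mean_threshold`, `gaps_covered` (list column of gap
#'   row indices), `n_gaps`, `retained`.
#' @export
audit_coverage <- function(candidates, gaps) {
  stopifnot(inherits(candidates, "threshold_map"), inherits(gaps, "gap_set"))
  cand <- candidates$items[!candidates$items$is_reference, , drop = FALSE]
  covered <- lapply(cand$id, function(id) {
    th <- candidates$thresholds[[id]]
    if (!nrow(gaps)) return(integer(0))
    which(vapply(seq_len(nrow(gaps)), function(g) {
      any(th >= gaps$lower[g] & th <= gaps$upper[g])
    }, logical(1)))
  })
  out <- data.frame(id = cand$id, domain = cand$domain,
                    mean_threshold = cand$mean_threshold,
                    stringsAsFactors = FALSE)
  out$gaps_covered <- covered
  out$n_gaps <- lengths(covered)
  out$retained <- out$n_gaps > 0L
  class(out) <- c("coverage_audit", "data.frame")
  out
}

#' Domain-balanced greedy selection of gap-filling items
#'
#' Greedy set cover with domain balancing: iteratively select the candidate
#' covering the most still-uncovered gaps, breaking ties by (1) the domain
#' least represented among already-selected plus reference items, (2) lower
#' mean severity, (3) lexicographic id; stop when every coverable gap is
#' covered or candidates are exhausted.  `force_include` / `force_exclude`
#' allow a published scale composition to be expressed exactly.
#'
#' @param audit a `coverage_audit` (or data frame with columns `id`,
#'   `domain`, `mean_threshold`, `gaps_covered`).
#' @param n_gaps total number of gaps audited.
#' @param reference_domains character vector of the reference items'
#'   domains (used by the balancing tie-break).
#' @param force_include,force_exclude item ids to force in or out.
#' @return An object of class `selection_result`: list with `selected`
#'   (ids, in selection order), `per_item` (data frame id/domain/gaps),
#'   `gap_status` (data frame gap/covered_by), `uncovered` (gap indices no
#'   candidate covers), `domain_tally` (table over reference + selected).
#' @export
select_items <- function(audit, n_gaps, reference_domains = character(0),
                         force_include = character(0),
                         force_exclude = character(0)) {
  stopifnot(is.data.frame(audit))
  audit <- audit[!audit$id %in% force_exclude, , drop = FALSE]
  gaps_cov <- stats::setNames(audit$gaps_covered, audit$id)
  domains <- stats::setNames(audit$domain, audit$id)
  severity <- stats::setNames(audit$mean_threshold, audit$id)
  coverable <- sort(unique(unlist(gaps_cov)))
  uncoverable <- setdiff(seq_len(n_gaps), coverable)

  selected <- character(0)
  uncovered <- coverable
  for (id in intersect(force_include, audit$id)) {
    selected <- c(selected, id)
    uncovered <- setdiff(uncovered, gaps_cov[[id]])
  }
  pool <- setdiff(audit$id, selected)
  while (length(uncovered) && length(pool)) {
    gain <- vapply(pool, function(id)
      length(intersect(gaps_cov[[id]], uncovered)), integer(1))
    if (max(gain) == 0L) break
    best <- pool[gain == max(gain)]
    if (length(best) > 1L) {
      # domain least represented among reference + already selected
      rep_count <- vapply(domains[best], function(d)
        sum(c(reference_domains, domains[selected]) == d), numeric(1))
      best <- best[rep_count == min(rep_count)]
    }
    if (length(best) > 1L)
      best <- best[severity[best] == min(severity[best])]
    if (length(best) > 1L) best <- sort(best)[1L]
    selected <- c(selected, best[1L])
    uncovered <- setdiff(uncovered, gaps_cov[[best[1L]]])
    pool <- setdiff(pool, best[1L])
  }
  covered_by <- lapply(seq_len(n_gaps), function(g)
    selected[vapply(selected, function(id) g %in% gaps_cov[[id]],
                    logical(1))])
  tally <- table(c(reference_domains, unname(domains[selected])))
  structure(list(
    selected = selected,
    per_item = data.frame(id = selected,
                          domain = unname(domains[selected]),
                          n_gaps = lengths(gaps_cov[selected]),
                          stringsAsFactors = FALSE),
    gap_status = data.frame(gap = seq_len(n_gaps),
                            covered = lengths(covered_by) > 0L),
    uncovered = union(uncoverable, uncovered),
    domain_tally = tally),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Selected", length(x$selected), "item(s):",
      paste(x$selected, collapse = ", "), "\n")
  if (length(x$uncovered))
    cat("  uncovered gap(s):", paste(x$uncovered, collapse = ", "), "\n")
  invisible(x)
}

#' Interrater agreement (kappa) for domain categorization
#'
#' Chance-corrected agreement among raters assigning items to categorical
#' domains: Fleiss' kappa for three or more raters, Cohen's kappa for
#' exactly two.  `method = "mean_pairwise"` averages Cohen's kappa over all
#' rater pairs (an alternative multi-rater summary).
#'
#' @param ratings items x raters matrix (or data frame) of categorical
#'   labels.
#' @param method `"auto"` (Fleiss for >= 3 raters, Cohen for 2),
#'   `"fleiss"`, `"cohen"`, or `"mean_pairwise"`.
#' @return Kappa in `[-1, 1]`.
#' @export
rater_kappa <- function(ratings, method = c("auto", "fleiss", "cohen",
                                            "mean_pairwise")) {
  method <- match.arg(method)
  ratings <- as.matrix(ratings)
  if (ncol(ratings) < 2L) stop("need at least 2 raters")
  if (nrow(ratings) < 2L) stop("need at least 2 items")
  cats <- sort(unique(as.vector(ratings)))
  if (length(cats) < 2L)
    stop("kappa undefined: a single category was used throughout")
  if (method == "auto")
    method <- if (ncol(ratings) >= 3L) "fleiss" else "cohen"
  if (method == "cohen") {
    if (ncol(ratings) != 2L) stop("Cohen's kappa needs exactly 2 raters")
    return(cohen_kappa(ratings[, 1L], ratings[, 2L], cats))
  }
  if (method == "mean_pairwise") {
    pairs <- utils::combn(ncol(ratings), 2L)
    return(mean(apply(pairs, 2L, function(pr)
      cohen_kappa(ratings[, pr[1L]], ratings[, pr[2L]], cats))))
  }
  # Fleiss: n items, m raters
  m <- ncol(ratings)
  nij <- t(apply(ratings, 1L, function(row)
    vapply(cats, function(cc) sum(row == cc), numeric(1))))
  Pi <- (rowSums(nij^2) - m) / (m * (m - 1))
  Pbar <- mean(Pi)
  pj <- colSums(nij) / (nrow(ratings) * m)
  Pe <- sum(pj^2)
  if (1 - Pe < 1e-12)
    stop("kappa undefined: no category variability")
  (Pbar - Pe) / (1 - Pe)
}

cohen_kappa <- function(a, b, cats) {
  tab <- table(factor(a, levels = cats), factor(b, levels = cats))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - pe < 1e-12) stop("kappa undefined: no category variability")
  (po - pe) / (1 - pe)
}
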