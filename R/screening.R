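#' Add-one-item candidate screening
#'
#' For each candidate item, fits a separate one-factor categorical CFA on
#' the base items plus that single candidate and records the candidate's
#' loading; candidates are retained when the loading is greater than or
#' equal to the cutoff (default 0.45).  A final combined one-factor model is
#' then fitted on the base plus all retained items.  Candidates are
#' evaluated independently, one at a time, so the screen is order-invariant.
#'
#' The full polychoric matrix over base and candidates is computed once and
#' submatrices are reused across the per-candidate fits; pairwise tables do
#' not depend on which other items are present, so this is exactly
#' equivalent to refitting each add-one model from the raw data.
#'
#' @param base character vector of base (reference) item ids.
#' @param candidates character vector of candidate item ids, disjoint from
#'   `base` (duplicates of base items must be removed beforehand, e.g. with
#'   [dedupe_candidates()]).
#' @param responses a [response_matrix] containing all items.
#' @param cutoff retention loading cutoff; the comparison is `>= cutoff`.
#' @param estimator passed to [fit_cfa()].
#' @return An object of class `red_screen`: list with `table` (data frame:
#'   candidate, loading, retained, evaluable), `combined` (the base +
#'   retained `red_cfa`), `cutoff`, `base`.
#' @export
screen_candidates <- function(base, candidates, responses, cutoff = 0.45,
                              estimator = c("uls", "dwls")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(responses, "response_matrix"))
  if (length(intersect(base, candidates)))
    stop("base and candidate sets overlap: ",
         paste(intersect(base, candidates), collapse = ", "))
  all_items <- c(base, candidates)
  missing_it <- setdiff(all_items, colnames(responses$values))
  if (length(missing_it)) stop("item(s) not in responses: ",
                               paste(missing_it, collapse = ", "))
  deg <- degenerate_items(subset_items(responses, all_items))
  bad_cand <- candidates[candidates %in% names(deg)[deg]]
  if (length(bad_cand))
    warning("excluding degenerate candidate(s): ",
            paste(bad_cand, collapse = ", "))
  if (any(deg[base]))
    stop("degenerate base item(s): ",
         paste(base[deg[base]], collapse = ", "))
  eval_cand <- setdiff(candidates, bad_cand)

  poly_all <- polychoric_matrix(subset_items(responses, c(base, eval_cand)))
  sub_poly <- function(ids) {
    structure(list(thresholds = poly_all$thresholds[ids],
                   mapping = poly_all$mapping[ids],
                   corr = poly_all$corr[ids, ids],
                   pairwise_n = poly_all$pairwise_n[ids, ids],
                   smoothed = poly_all$smoothed,
                   items = ids, n = poly_all$n),
              class = "red_poly")
  }
  spec1 <- model_spec("ONE_FACTOR")
  loading <- rep(NA_real_, length(candidates))
  evaluable <- !candidates %in% bad_cand
  names(loading) <- names(evaluable) <- candidates
  for (cand in eval_cand) {
    fit <- tryCatch(
      suppressWarnings(fit_cfa(sub_poly(c(base, cand)), spec1, estimator)),
      error = function(e) NULL)
    if (is.null(fit)) {
      evaluable[cand] <- FALSE
    } else {
      loading[cand] <- fit$loadings[[cand]]
    }
  }
  retained <- !is.na(loading) & loading >= cutoff
  keep <- candidates[retained]
  combined <- suppressWarnings(
    fit_cfa(sub_poly(c(base, keep)), spec1, estimator))
  combined$fit_indices <- fit_indices(
    combined, fit_baseline(sub_poly(c(base, keep)), estimator))
  combined$responses <- subset_items(responses, c(base, keep))
  structure(list(
    table = data.frame(candidate = candidates,
                       loading = unname(loading),
                       retained = unname(retained),
                       evaluable = unname(evaluable),
                       stringsAsFactors = FALSE),
    combined = combined, cutoff = cutoff, base = base),
    class = "red_screen")
}

#' @export
print.red_screen <- function(x, ...) {
  cat("Screening:", nrow(x$table), "candidates against",
      length(x$base), "base items; cutoff >=", x$cutoff, "\n")
  cat("  retained:", sum(x$table$retained), "; not evaluable:",
      sum(!x$table$evaluable), "\n")
  invisible(x)
}

#' Merge candidate id sets, dropping overlaps
#'
#' Union of two candidate pools preserving first-seen order, with the
#' overlap accounting used when pooling items retained in different studies
#' (e.g. 15 + 37 retained items with 5 overlaps give 47 for consideration).
#'
#' @param setA,setB character vectors of canonicalized item ids.
#' @return The merged unique ids, with attribute `"counts"`:
#'   list(`n_a`, `n_b`, `overlap`, `union`).
#' @export
dedupe_candidates <- function(setA, setB) {
  setA <- as.character(setA)
  setB <- as.character(setB)
  merged <- unique(c(setA, setB))
  structure(merged,
            counts = list(n_a = length(unique(setA)),
                          n_b = length(unique(setB)),
                          overlap = length(intersect(unique(setA),
                                                     unique(setB))),
                          union = length(merged)))
}
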