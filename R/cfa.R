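#' Model specification for categorical CFA
#'
#' Identification follows the conventional categorical-CFA scheme: factor
#' variances fixed to 1, loadings free, factor correlations free.  For the
#' three-factor structure each item is assigned to exactly one of the three
#' RRE domains.
#'
#' @param structure `"ONE_FACTOR"` or `"THREE_FACTOR"`.
#' @param assignments named character vector mapping item id to factor name
#'   (required for `THREE_FACTOR`; factor names as in [red_factor_names()]).
#' @return An object of class `red_model_spec`.
#' @export
model_spec <- function(structure = c("ONE_FACTOR", "THREE_FACTOR"),
                       assignments = NULL) {
  structure <- match.arg(structure)
  if (structure == "THREE_FACTOR") {
    if (is.null(assignments))
      stop("THREE_FACTOR needs item -> factor assignments")
    bad <- !assignments %in% red_factor_names()
    if (any(bad))
      stop("unknown factor for item ", names(assignments)[bad][1L])
  }
  structure(list(structure = structure, assignments = assignments),
            class = "red_model_spec")
}

#' Fit a confirmatory factor model to a polychoric matrix
#'
#' Minimizes the least-squares discrepancy
#' `F = sum_{i<j} w_ij (rho_ij - sigma_ij)^2` with model-implied
#' `sigma_ij = lambda_i lambda_j psi_{d(i) d(j)}`, by quasi-Newton
#' optimization with analytic gradient from the documented start
#' (all loadings 0.5, factor correlations 0.5).  Weights are 1 under ULS or
#' inverse asymptotic variances of the polychoric correlations under DWLS.
#' The chi-square statistic is the unscaled `(n_effective - 1) * F_min`; no
#' mean-and-variance (robust) adjustment is applied, so printed fit indices
#' are not comparable to software that scales the test statistic.
#'
#' Sign indeterminacy is resolved by constraining the first loading on each
#' factor to be nonnegative.  Loadings reaching the 0.995 boundary (Heywood
#' cases) are reported with a warning.
#'
#' @param poly a `red_poly` from [polychoric_matrix()].
#' @param spec a [model_spec()].
#' @param estimator `"uls"` or `"dwls"`.
#' @return An object of class `red_cfa`; see [red_cfa()] for the fields.
#' @export
fit_cfa <- function(poly, spec, estimator = c("uls", "dwls")) {
  stopifnot(inherits(poly, "red_poly"), inherits(spec, "red_model_spec"))
  estimator <- match.arg(estimator)
  items <- poly$items
  p <- length(items)
  if (spec$structure == "THREE_FACTOR") {
    miss <- setdiff(items, names(spec$assignments))
    if (length(miss)) stop("no factor assignment for item(s): ",
                           paste(miss, collapse = ", "))
    fac <- match(spec$assignments[items], red_factor_names())
    nfac <- 3L
  } else {
    fac <- rep(1L, p)
    nfac <- 1L
  }

  ut <- which(upper.tri(poly$corr), arr.ind = TRUE)
  ii <- ut[, 1L]; jj <- ut[, 2L]
  r <- poly$corr[ut]
  w <- if (estimator == "dwls") {
    vapply(seq_len(nrow(ut)), function(q) {
      polychoric_unit_info(poly$thresholds[[ii[q]]],
                           poly$thresholds[[jj[q]]], r[q])
    }, numeric(1))
  } else rep(1, nrow(ut))

  # free factor correlations: the distinct factor pairs spanned by the items
  pair_id <- ifelse(fac[ii] < fac[jj],
                    paste(fac[ii], fac[jj]), paste(fac[jj], fac[ii]))
  psi_pairs <- if (nfac > 1L) sort(unique(pair_id[fac[ii] != fac[jj]])) else
    character(0)
  npsi <- length(psi_pairs)
  psi_idx <- match(pair_id, psi_pairs)   # NA for same-factor pairs

  obj <- function(par) {
    lam <- par[seq_len(p)]
    psi <- if (npsi) par[p + seq_len(npsi)] else numeric(0)
    psi_ij <- ifelse(is.na(psi_idx), 1, psi[psi_idx])
    e <- r - lam[ii] * lam[jj] * psi_ij
    sum(w * e^2)
  }
  grad <- function(par) {
    lam <- par[seq_len(p)]
    psi <- if (npsi) par[p + seq_len(npsi)] else numeric(0)
    psi_ij <- ifelse(is.na(psi_idx), 1, psi[psi_idx])
    e <- r - lam[ii] * lam[jj] * psi_ij
    glam <- numeric(p)
    common <- -2 * w * e * psi_ij
    for (q in seq_along(e)) {
      glam[ii[q]] <- glam[ii[q]] + common[q] * lam[jj[q]]
      glam[jj[q]] <- glam[jj[q]] + common[q] * lam[ii[q]]
    }
    gpsi <- numeric(npsi)
    if (npsi) {
      contrib <- -2 * w * e * lam[ii] * lam[jj]
      for (q in seq_along(e)) {
        if (!is.na(psi_idx[q]))
          gpsi[psi_idx[q]] <- gpsi[psi_idx[q]] + contrib[q]
      }
    }
    c(glam, gpsi)
  }

  lower <- rep(-0.995, p)
  upper <- rep(0.995, p)
  # first item on each factor anchored nonnegative
  for (f in unique(fac)) lower[which(fac == f)[1L]] <- 0
  if (npsi) {
    lower <- c(lower, rep(-0.999, npsi))
    upper <- c(upper, rep(0.999, npsi))
  }
  start <- c(rep(0.5, p), rep(0.5, npsi))
  fit <- stats::nlminb(start, obj, grad, lower = lower, upper = upper,
                       control = list(iter.max = 500L, eval.max = 2000L,
                                      abs.tol = 1e-10, rel.tol = 1e-12))
  if (fit$convergence != 0 &&
      !grepl("converg|relative", tolower(fit$message %||% "")))
    stop("CFA did not converge: ", fit$message)
  lam <- stats::setNames(fit$par[seq_len(p)], items)
  if (any(abs(lam) >= 0.995 - 1e-8))
    warning("Heywood case: loading(s) at the 0.995 bound for item(s) ",
            paste(items[abs(lam) >= 0.995 - 1e-8], collapse = ", "))
  psi_hat <- diag(nfac)
  if (npsi) {
    psi <- fit$par[p + seq_len(npsi)]
    for (q in seq_len(npsi)) {
      ab <- as.integer(strsplit(psi_pairs[q], " ")[[1L]])
      psi_hat[ab[1L], ab[2L]] <- psi_hat[ab[2L], ab[1L]] <- psi[q]
    }
  }
  if (nfac == 3L) dimnames(psi_hat) <- list(red_factor_names(),
                                            red_factor_names())
  F_min <- fit$objective
  n_eff <- round(mean(poly$pairwise_n[upper.tri(poly$pairwise_n)]))
  nfree <- p + npsi
  df <- p * (p - 1L) / 2L - nfree
  psi_ij <- ifelse(is.na(psi_idx), 1,
                   if (npsi) fit$par[p + psi_idx] else 1)
  sigma <- lam[ii] * lam[jj] * psi_ij
  resid <- matrix(0, p, p, dimnames = dimnames(poly$corr))
  resid[ut] <- r - sigma
  resid <- resid + t(resid)
  structure(list(loadings = lam, thresholds = poly$thresholds,
                 factor_corr = psi_hat, factors = stats::setNames(fac, items),
                 structure = spec$structure, estimator = estimator,
                 discrepancy = F_min,
                 chi2 = (n_eff - 1) * F_min, df = df,
                 n_effective = n_eff, residual_corr = resid,
                 srmr_raw = sqrt(mean((r - sigma)^2)),
                 poly = poly, spec = spec, fit_indices = NULL),
            class = "red_cfa")
}

#' Incremental and residual fit indices
#'
#' Computes CFI, RMSEA and SRMR from a fitted model and the independence
#' (zero-correlation) baseline on the same items and sample:
#' `CFI = 1 - max(chi2_M - df_M, 0) / max(chi2_B - df_B, chi2_M - df_M, 0)`;
#' `RMSEA = sqrt(max(chi2_M - df_M, 0) / (df_M (n - 1)))`;
#' `SRMR = sqrt(mean over i<j of squared correlation residuals)`.
#' Conventional cut-offs in this literature are CFI > 0.95, RMSEA < 0.06 and
#' SRMR < 0.08; the indices are reported, never enforced.
#'
#' @param fit a `red_cfa`.
#' @param baseline a `red_cfa` of the independence model on the same items
#'   (see [fit_baseline()]).
#' @return Named list `CFI`, `RMSEA`, `SRMR`.
#' @export
fit_indices <- function(fit, baseline) {
  stopifnot(inherits(fit, "red_cfa"), inherits(baseline, "red_cfa"))
  if (fit$df <= 0) stop("fit indices undefined: model df <= 0")
  n <- fit$n_effective
  num <- max(fit$chi2 - fit$df, 0)
  den <- max(baseline$chi2 - baseline$df, fit$chi2 - fit$df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  rmsea <- sqrt(max(fit$chi2 - fit$df, 0) / (fit$df * (n - 1)))
  list(CFI = cfi, RMSEA = rmsea, SRMR = fit$srmr_raw)
}

#' Independence baseline model
#'
#' The zero-correlation model used as the CFI baseline: all model-implied
#' correlations are 0, no free structural parameters, df = p(p-1)/2.
#'
#' @inheritParams fit_cfa
#' @return A minimal `red_cfa` carrying `chi2` and `df`.
#' @export
fit_baseline <- function(poly, estimator = c("uls", "dwls")) {
  estimator <- match.arg(estimator)
  ut <- upper.tri(poly$corr)
  r <- poly$corr[ut]
  p <- length(poly$items)
  w <- if (estimator == "dwls") {
    idx <- which(ut, arr.ind = TRUE)
    vapply(seq_len(nrow(idx)), function(q) {
      polychoric_unit_info(poly$thresholds[[idx[q, 1L]]],
                           poly$thresholds[[idx[q, 2L]]], r[q])
    }, numeric(1))
  } else rep(1, sum(ut))
  F_b <- sum(w * r^2)
  n_eff <- round(mean(poly$pairwise_n[ut]))
  structure(list(loadings = stats::setNames(rep(0, p), poly$items),
                 thresholds = poly$thresholds, factor_corr = diag(1),
                 structure = "INDEPENDENCE", estimator = estimator,
                 discrepancy = F_b, chi2 = (n_eff - 1) * F_b,
                 df = p * (p - 1L) / 2L, n_effective = n_eff,
                 srmr_raw = sqrt(mean(r^2)), poly = poly),
            class = "red_cfa")
}

#' Categorical confirmatory factor analysis of ordinal responses
#'
#' The package's central fitting function: estimates thresholds and
#' polychoric correlations from an ordinal [response_matrix], fits a one- or
#' three-factor model by (diagonally weighted) least squares, and attaches
#' CFI/RMSEA/SRMR computed against the independence baseline.
#'
#' @param responses a [response_matrix].
#' @param structure `"ONE_FACTOR"` or `"THREE_FACTOR"` (three-factor
#'   assignments default to the bank's `domain` column).
#' @param estimator `"uls"` (default) or `"dwls"`.
#' @param items optional subset of item ids to fit.
#' @return An object of class `red_cfa` with components `loadings`,
#'   `thresholds`, `factor_corr`, `discrepancy`, `chi2`, `df`,
#'   `fit_indices` (list CFI/RMSEA/SRMR), `n_effective`, `residual_corr`,
#'   `poly`, and the originating `responses`.  Supports `print()`,
#'   `summary()`, `coef()`, `residuals()`, `predict()` (EAP person
#'   locations) and `plot()` (person-item map).
#' @examples
#' study <- simulate_study("STUDY34_LIKE", n = 200, seed = 42)
#' fit <- red_cfa(study$responses, structure = "ONE_FACTOR")
#' fit
#' @export
red_cfa <- function(responses, structure = c("ONE_FACTOR", "THREE_FACTOR"),
                    estimator = c("uls", "dwls"), items = NULL) {
  structure <- match.arg(structure)
  estimator <- match.arg(estimator)
  stopifnot(inherits(responses, "response_matrix"))
  if (!is.null(items)) responses <- subset_items(responses, items)
  assignments <- if (structure == "THREE_FACTOR") {
    stats::setNames(responses$bank$domain, responses$bank$id)
  } else NULL
  spec <- model_spec(structure, assignments)
  poly <- polychoric_matrix(responses)
  fit <- fit_cfa(poly, spec, estimator)
  fit$fit_indices <- fit_indices(fit, fit_baseline(poly, estimator))
  fit$responses <- responses
  fit
}

#' @export
print.red_cfa <- function(x, ...) {
  cat(sprintf("Categorical CFA (%s, %s): %d items, n = %d\n",
              tolower(x$structure), toupper(x$estimator),
              length(x$loadings), x$n_effective))
  cat(sprintf("  chi2 = %.3f, df = %d", x$chi2, x$df))
  if (!is.null(x$fit_indices))
    cat(sprintf(", CFI = %.3f, RMSEA = %.3f, SRMR = %.3f",
                x$fit_indices$CFI, x$fit_indices$RMSEA, x$fit_indices$SRMR))
  cat("\n")
  invisible(x)
}

#' @export
summary.red_cfa <- function(object, ...) {
  print(object)
  tab <- data.frame(
    item = names(object$loadings),
    loading = round(unname(object$loadings), 3),
    mean_threshold = round(vapply(object$thresholds, mean, numeric(1)), 3),
    n_thresholds = vapply(object$thresholds, length, integer(1))
  )
  print(tab, row.names = FALSE)
  if (object$structure == "THREE_FACTOR") {
    cat("Factor correlations:\n")
    print(round(object$factor_corr, 3))
  }
  invisible(object)
}

#' @export
coef.red_cfa <- function(object, ...) object$loadings

#' @export
residuals.red_cfa <- function(object, ...) object$residual_corr
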