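#' Estimate item thresholds from category counts
#'
#' The threshold for boundary c is the point on the latent standard-normal
#' continuum where a respondent is 50% likely to endorse category c or
#' higher: `tau_c = qnorm(cumulative proportion through category c)`,
#' c = 1 ... k-1.
#'
#' Categories observed with zero count are collapsed into the adjacent lower
#' category (the lowest category collapses upward) with a warning; the
#' returned vector then has one threshold per remaining boundary and carries
#' the code mapping as attribute `"mapping"` (old 0-based code -> collapsed
#' 0-based code).  If fewer than two categories carry mass there is no
#' estimable threshold and an error is raised.
#'
#' @param counts nonnegative counts of length k (category frequencies,
#'   lowest category first).
#' @return Numeric vector of strictly increasing thresholds, with attribute
#'   `"mapping"`.
#' @examples
#' estimate_thresholds(c(20, 20, 20, 20, 20))  # normal quintiles
#' @export
estimate_thresholds <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || sum(counts) <= 0)
    stop("counts must be nonnegative with positive total")
  k <- length(counts)
  nonzero <- counts > 0
  if (sum(nonzero) < 2L)
    stop("no estimable threshold: all responses fall in one category")
  mapping <- collapse_mapping(counts)
  collapsed <- as.numeric(tapply(counts, mapping, sum))
  if (any(!nonzero))
    warning("collapsed ", sum(!nonzero), " zero-count categor",
            if (sum(!nonzero) > 1) "ies" else "y",
            " into adjacent categories")
  p <- cumsum(collapsed) / sum(collapsed)
  tau <- stats::qnorm(p[-length(p)])
  attr(tau, "mapping") <- mapping
  tau
}

# 0-based old code -> 0-based collapsed code; zero-count categories merge
# into the nearest lower nonzero category (the leading run merges upward)
collapse_mapping <- function(counts) {
  k <- length(counts)
  new_code <- integer(k)
  cur <- -1L
  for (c in seq_len(k)) {
    if (counts[c] > 0) cur <- cur + 1L
    new_code[c] <- max(cur, 0L)
  }
  stats::setNames(new_code, 0:(k - 1L))
}

# bivariate standard-normal CDF at possibly infinite corners
pbvn <- function(x, y, rho) {
  if (is.infinite(x) && x < 0) return(0)
  if (is.infinite(y) && y < 0) return(0)
  if (is.infinite(x)) return(stats::pnorm(y))
  if (is.infinite(y)) return(stats::pnorm(x))
  mvtnorm::pmvnorm(upper = c(x, y),
                   corr = matrix(c(1, rho, rho, 1), 2),
                   algorithm = mvtnorm::Miwa(steps = 128))[1]
}

# cell probabilities of a k1 x k2 contingency table under a bivariate normal
# with thresholds tau1/tau2 and correlation rho
bvn_cell_probs <- function(tau1, tau2, rho) {
  a <- c(-Inf, tau1, Inf)
  b <- c(-Inf, tau2, Inf)
  k1 <- length(tau1) + 1L
  k2 <- length(tau2) + 1L
  cdf <- matrix(0, k1 + 1L, k2 + 1L)
  for (r in seq_len(k1 + 1L)) for (c in seq_len(k2 + 1L))
    cdf[r, c] <- pbvn(a[r], b[c], rho)
  P <- cdf[-1L, -1L, drop = FALSE] - cdf[-(k1 + 1L), -1L, drop = FALSE] -
    cdf[-1L, -(k2 + 1L), drop = FALSE] +
    cdf[-(k1 + 1L), -(k2 + 1L), drop = FALSE]
  pmax(P, 0)
}

#' Polychoric correlation of one item pair
#'
#' Two-step maximum likelihood: thresholds are fixed at their marginal
#' estimates ([estimate_thresholds()] on the table margins) and the latent
#' correlation rho maximizes the multinomial likelihood of the table under a
#' standard bivariate normal, with cell probabilities given by rectangle
#' probabilities between consecutive thresholds.  rho is found by a bounded
#' scalar optimizer to tolerance 1e-6.
#'
#' @param table k1 x k2 contingency table of nonnegative counts.
#' @param tau1,tau2 optional fixed thresholds; by default estimated from the
#'   table margins (zero-margin rows/columns are collapsed with a warning).
#' @return Estimated correlation in (-1, 1), with attribute `"loglik"`.
#' @examples
#' polychoric_pair(matrix(c(40, 10, 10, 40), 2))  # = sin(0.3 * pi)
#' @export
polychoric_pair <- function(table, tau1 = NULL, tau2 = NULL) {
  tab <- as.matrix(table)
  if (any(tab < 0)) stop("table counts must be nonnegative")
  if (sum(tab) <= 0) stop("empty table")
  rmarg <- rowSums(tab)
  cmarg <- colSums(tab)
  if (is.null(tau1)) {
    tau1 <- estimate_thresholds(rmarg)
    tab <- rowsum(tab, attr(tau1, "mapping")[seq_along(rmarg)])
  }
  if (is.null(tau2)) {
    tau2 <- estimate_thresholds(cmarg)
    tab <- t(rowsum(t(tab), attr(tau2, "mapping")[seq_along(cmarg)]))
  }
  if (sum(tab > 0) == 1L) {
    warning("all mass in one cell; correlation clamped")
    rho <- if (which(tab > 0) == 1L || which(tab > 0) == length(tab))
      1 - 1e-6 else -(1 - 1e-6)
    return(structure(rho, loglik = 0))
  }
  negll <- function(rho) {
    P <- bvn_cell_probs(tau1, tau2, rho)
    -sum(tab * log(pmax(P, 1e-12)))
  }
  opt <- stats::optimize(negll, c(-1 + 1e-6, 1 - 1e-6), tol = 1e-6)
  structure(opt$minimum, loglik = -opt$objective)
}

#' Polychoric correlation matrix of a response matrix
#'
#' Builds pairwise-complete contingency tables (pairwise deletion for
#' missing values), estimates each pair's polychoric correlation by
#' [polychoric_pair()], and assembles the item correlation matrix.  If the
#' smallest eigenvalue falls below 1e-8, eigenvalue-clipping smoothing is
#' applied (eigenvalues floored, matrix rescaled to unit diagonal) and the
#' result is flagged.
#'
#' @param rm a [response_matrix] with at least 2 non-degenerate items.
#' @param min_pairs minimum complete pairs required per item pair.
#' @return An object of class `red_poly`: list with `thresholds` (per item,
#'   from full-sample margins), `mapping` (per-item collapsed code maps),
#'   `corr`, `pairwise_n`, `smoothed`, `items`, `n`.
#' @export
polychoric_matrix <- function(rm, min_pairs = 10L) {
  stopifnot(inherits(rm, "response_matrix"))
  deg <- degenerate_items(rm)
  if (any(deg))
    stop("degenerate item(s) with < 2 observed categories: ",
         paste(names(deg)[deg], collapse = ", "))
  v <- rm$values
  p <- ncol(v)
  if (p < 2L) stop("need at least 2 items")
  items <- colnames(v)
  ks <- rm$bank$n_options
  thresholds <- vector("list", p)
  mapping <- vector("list", p)
  for (i in seq_len(p)) {
    counts <- tabulate(v[, i] + 1L, nbins = ks[i])
    tau <- suppressWarnings(estimate_thresholds(counts))
    thresholds[[i]] <- as.numeric(tau)
    mapping[[i]] <- attr(tau, "mapping")
  }
  names(thresholds) <- names(mapping) <- items
  corr <- diag(p)
  pairwise_n <- matrix(nrow(v), p, p)
  near_singular <- matrix(FALSE, p, p)
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      ok <- !is.na(v[, i]) & !is.na(v[, j])
      n_ij <- sum(ok)
      if (n_ij < min_pairs)
        stop(sprintf("items '%s' and '%s' share only %d complete pairs",
                     items[i], items[j], n_ij))
      tab <- table(factor(v[ok, i], levels = 0:(ks[i] - 1L)),
                   factor(v[ok, j], levels = 0:(ks[j] - 1L)))
      r <- suppressWarnings(polychoric_pair(tab))
      corr[i, j] <- corr[j, i] <- as.numeric(r)
      pairwise_n[i, j] <- pairwise_n[j, i] <- n_ij
      near_singular[i, j] <- near_singular[j, i] <- abs(r) > 1 - 1e-4
    }
  }
  dimnames(corr) <- dimnames(pairwise_n) <- list(items, items)
  smoothed <- FALSE
  ev <- eigen(corr, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    lam <- pmax(ev$values, 1e-8)
    corr <- ev$vectors %*% diag(lam) %*% t(ev$vectors)
    d <- sqrt(diag(corr))
    corr <- corr / tcrossprod(d)
    dimnames(corr) <- list(items, items)
    smoothed <- TRUE
  }
  structure(list(thresholds = thresholds, mapping = mapping, corr = corr,
                 pairwise_n = pairwise_n, smoothed = smoothed,
                 near_singular = near_singular, items = items,
                 n = nrow(v)),
            class = "red_poly")
}

#' @export
print.red_poly <- function(x, ...) {
  cat("Polychoric model:", length(x$items), "items, n =", x$n,
      if (x$smoothed) "(smoothed)" else "", "\n")
  invisible(x)
}

# Fisher information of rho for one pair at fixed thresholds, per
# observation: I(rho) = sum_cells (dP/drho)^2 / P, using
# dPhi2(x, y; rho)/drho = phi2(x, y; rho) at the cell corners.
# Used for DWLS weights (inverse asymptotic variances).
polychoric_unit_info <- function(tau1, tau2, rho) {
  a <- c(-Inf, tau1, Inf)
  b <- c(-Inf, tau2, Inf)
  phi2 <- function(x, y) {
    if (is.infinite(x) || is.infinite(y)) return(0)
    exp(-(x^2 - 2 * rho * x * y + y^2) / (2 * (1 - rho^2))) /
      (2 * pi * sqrt(1 - rho^2))
  }
  k1 <- length(tau1) + 1L
  k2 <- length(tau2) + 1L
  dens <- matrix(0, k1 + 1L, k2 + 1L)
  for (r in seq_len(k1 + 1L)) for (c in seq_len(k2 + 1L))
    dens[r, c] <- phi2(a[r], b[c])
  dP <- dens[-1L, -1L, drop = FALSE] - dens[-(k1 + 1L), -1L, drop = FALSE] -
    dens[-1L, -(k2 + 1L), drop = FALSE] +
    dens[-(k1 + 1L), -(k2 + 1L), drop = FALSE]
  P <- bvn_cell_probs(tau1, tau2, rho)
  sum(dP^2 / pmax(P, 1e-12))
}
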