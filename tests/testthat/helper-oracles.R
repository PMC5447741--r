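# Independent oracles used across the suite.

# Bivariate-normal CDF over a fine grid of correlations, by integrating the
# identity dPhi2(x, y; rho)/drho = phi2(x, y; rho) outward from rho = 0
# (where Phi2 = Phi(x) Phi(y)).  Completely independent of the package's
# rectangle-probability code path.
phi2_density <- function(x, y, rho) {
  exp(-(x^2 - 2 * rho * x * y + y^2) / (2 * (1 - rho^2))) /
    (2 * pi * sqrt(1 - rho^2))
}

pbvn_grid <- function(x, y, rho_grid) {
  if (is.infinite(x) && x < 0) return(rep(0, length(rho_grid)))
  if (is.infinite(y) && y < 0) return(rep(0, length(rho_grid)))
  if (is.infinite(x)) return(rep(pnorm(y), length(rho_grid)))
  if (is.infinite(y)) return(rep(pnorm(x), length(rho_grid)))
  i0 <- which.min(abs(rho_grid))
  f <- phi2_density(x, y, rho_grid)
  out <- numeric(length(rho_grid))
  out[i0] <- pnorm(x) * pnorm(y)
  if (i0 < length(rho_grid)) {
    steps <- diff(rho_grid[i0:length(rho_grid)])
    inc <- (f[i0:(length(rho_grid) - 1L)] + f[(i0 + 1L):length(rho_grid)]) /
      2 * steps
    out[(i0 + 1L):length(rho_grid)] <- out[i0] + cumsum(inc)
  }
  if (i0 > 1L) {
    steps <- diff(rho_grid[1:i0])
    dec <- (f[1:(i0 - 1L)] + f[2:i0]) / 2 * steps
    out[1:(i0 - 1L)] <- out[i0] - rev(cumsum(rev(dec)))
  }
  out
}

# Exhaustive grid-search ML polychoric estimate at fixed marginal
# thresholds; step 1e-4 over (-0.9999, 0.9999).
grid_ml_polychoric <- function(tab, step = 1e-4) {
  tab <- as.matrix(tab)
  rho_grid <- seq(-0.9999, 0.9999, by = step)
  tau1 <- qnorm(cumsum(rowSums(tab))[-nrow(tab)] / sum(tab))
  tau2 <- qnorm(cumsum(colSums(tab))[-ncol(tab)] / sum(tab))
  a <- c(-Inf, tau1, Inf)
  b <- c(-Inf, tau2, Inf)
  k1 <- nrow(tab); k2 <- ncol(tab)
  cdf <- array(0, c(k1 + 1L, k2 + 1L, length(rho_grid)))
  for (r in seq_len(k1 + 1L)) for (cc in seq_len(k2 + 1L))
    cdf[r, cc, ] <- pbvn_grid(a[r], b[cc], rho_grid)
  P <- cdf[-1L, -1L, , drop = FALSE] - cdf[-(k1 + 1L), -1L, , drop = FALSE] -
    cdf[-1L, -(k2 + 1L), , drop = FALSE] +
    cdf[-(k1 + 1L), -(k2 + 1L), , drop = FALSE]
  P <- pmax(P, 1e-12)
  ll <- apply(log(P) * as.vector(tab), 3L, sum)
  rho_grid[which.max(ll)]
}

# All minimum-size covers of the coverable gaps: brute-force subset
# enumeration (fixtures keep <= 10 candidates).
exhaustive_min_covers <- function(gaps_covered) {
  ids <- names(gaps_covered)
  universe <- sort(unique(unlist(gaps_covered)))
  if (!length(universe)) return(list(character(0)))
  for (size in seq_along(ids)) {
    combos <- utils::combn(ids, size, simplify = FALSE)
    hits <- Filter(function(set) {
      length(setdiff(universe, unlist(gaps_covered[set]))) == 0L
    }, combos)
    if (length(hits)) return(hits)
  }
  list()
}
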