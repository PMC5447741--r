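#' Person locations on the latent trait (EAP factor scores)
#'
#' Expected a posteriori estimates under the fitted normal-ogive model with
#' a standard-normal prior, computed by Gauss-Hermite quadrature (49 nodes).
#' Items missing for a respondent are simply skipped in the likelihood
#' (pairwise use of information); a respondent with no observed items gets
#' the prior mean 0 and is flagged.
#'
#' For a three-factor fit, each factor is scored from its own items with a
#' standard-normal prior and the person location is the mean of the three
#' factor scores, matching the common single-total use of the scale.
#'
#' @param fit a `red_cfa` from [red_cfa()] or [fit_cfa()].
#' @param responses a [response_matrix]; defaults to the one stored in `fit`.
#' @param nodes number of Gauss-Hermite nodes.
#' @return Numeric vector of person locations, one per respondent, with
#'   attribute `"all_missing"` (logical vector) flagging prior-mean fallbacks.
#' @export
estimate_person_locations <- function(fit, responses = NULL, nodes = 49L) {
  stopifnot(inherits(fit, "red_cfa"))
  responses <- responses %||% fit$responses
  if (is.null(responses)) stop("no responses supplied or stored in fit")
  stopifnot(inherits(responses, "response_matrix"))
  items <- intersect(names(fit$loadings), colnames(responses$values))
  if (!length(items)) stop("fit and responses share no items")
  gh <- pracma::gaussHermite(nodes)
  theta_q <- sqrt(2) * gh$x
  wq <- gh$w / sqrt(pi)

  score_dim <- function(dim_items) {
    v <- responses$values[, dim_items, drop = FALSE]
    n <- nrow(v)
    loglik <- matrix(0, n, length(theta_q))
    for (it in dim_items) {
      lam <- fit$loadings[[it]]
      tau <- fit$poly$thresholds[[it]]
      map <- fit$poly$mapping[[it]]
      s <- sqrt(max(1 - lam^2, 1e-6))
      K <- length(tau) + 1L
      upper <- stats::pnorm(outer(-c(tau, Inf), lam * theta_q, "+") / s)
      lower <- stats::pnorm(outer(-c(-Inf, tau), lam * theta_q, "+") / s)
      Pmat <- pmax(lower - upper, 1e-12)      # K x Q, row c+1 = P(y = c)
      y <- v[, it]
      obs <- !is.na(y)
      if (!any(obs)) next
      code <- map[as.character(y[obs])]
      loglik[obs, ] <- loglik[obs, ] + log(Pmat)[code + 1L, , drop = FALSE]
    }
    post <- exp(loglik - apply(loglik, 1L, max))
    post <- post * rep(wq, each = n)
    rowSums(post * rep(theta_q, each = n)) / rowSums(post)
  }

  all_missing <- rowSums(!is.na(responses$values[, items, drop = FALSE])) == 0L
  if (fit$structure == "THREE_FACTOR") {
    per_fac <- lapply(sort(unique(fit$factors[items])), function(f) {
      dim_items <- items[fit$factors[items] == f]
      score_dim(dim_items)
    })
    theta <- Reduce(`+`, per_fac) / length(per_fac)
  } else {
    theta <- score_dim(items)
  }
  theta[all_missing] <- 0
  structure(theta, all_missing = all_missing,
            names = responses$respondent_ids)
}

#' @rdname estimate_person_locations
#' @param object a `red_cfa`.
#' @param newdata optional [response_matrix] to score.
#' @param ... unused.
#' @export
predict.red_cfa <- function(object, newdata = NULL, nodes = 49L, ...) {
  estimate_person_locations(object, responses = newdata, nodes = nodes)
}
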