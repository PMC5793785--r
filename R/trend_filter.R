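## First-order Poisson trend filtering with outlier detection.
##
## The background of an end-seq pileup window is modeled as a piecewise
## constant Poisson rate.  We minimize, over log-rates theta,
##
##     sum_i [ exp(theta_i) - c_i * theta_i ]  +  lambda * sum_i |theta_{i+1} - theta_i|
##
## (negative Poisson log-likelihood plus a first-order total-variation
## penalty).  The convex problem is solved by iteratively reweighted least
## squares: each outer step replaces the likelihood by its local quadratic
## approximation, giving a weighted 1-D fused lasso that ADMM solves exactly
## (sparse tridiagonal factorization, soft-threshold on adjacent
## differences).  The ADMM split variable is exactly sparse, so its zero
## pattern defines the segmentation; the reported background is the
## segment-wise Poisson MLE with flagged outliers excluded (post-selection
## debiasing, so a single segment reports the exact global mean and a fully
## unfused fit reproduces the counts).  Positions whose count has Poisson
## upper-tail probability below `outlier_p` under the current background are
## flagged, removed from the fit, and the fit repeated until the flag set
## stabilizes.

# exact weighted 1-D fused lasso:
#   min_theta 0.5 * sum w_i (theta_i - z_i)^2 + lambda * sum |theta_{i+1} - theta_i|
# returns list(theta, d) where d is the (exactly sparse) fitted difference
# vector; the ADMM iteration with its O(n) tridiagonal solve lives in C++
.weighted_fused_lasso <- function(z, w, lambda, max_iter = 2000L, tol = 1e-10,
                                  d0 = NULL, u0 = NULL) {
  admm_weighted_fused_lasso(as.numeric(z), as.numeric(w), lambda,
                            as.integer(max_iter), tol, d0, u0)
}

# one Poisson trend-filter solve for a fixed inclusion mask; returns the
# segment ids implied by the sparse difference vector.  The ADMM state
# (d, u) is warm-started across IRLS iterations (and, via `state`, across
# lambda values), which keeps the iteration counts small.
.solve_poisson_trend <- function(counts, lambda, mask, max_irls = 25L,
                                 state = NULL) {
  n <- length(counts)
  mu0 <- max(mean(counts[mask]), 1e-4)
  theta <- rep(log(mu0), n)
  d <- state$d; u <- state$u
  for (it in seq_len(max_irls)) {
    mu <- pmin(exp(theta), 1e8)
    w <- ifelse(mask, pmax(mu, 1e-6), 1e-8)
    z <- theta + ifelse(mask, (counts - mu) / pmax(mu, 1e-6), 0)
    fit <- .weighted_fused_lasso(z, w, lambda, max_iter = 250L, tol = 1e-9,
                                 d0 = d, u0 = u)
    delta <- max(abs(fit$theta - theta))
    theta <- fit$theta
    d <- fit$d; u <- fit$u
    if (delta < 1e-7) break
  }
  # polish: drive the ADMM to full convergence at the final IRLS weights so
  # the zero pattern of d (the segmentation) is trustworthy
  mu <- pmin(exp(theta), 1e8)
  w <- ifelse(mask, pmax(mu, 1e-6), 1e-8)
  z <- theta + ifelse(mask, (counts - mu) / pmax(mu, 1e-6), 0)
  fit <- .weighted_fused_lasso(z, w, lambda, max_iter = 5000L, tol = 1e-11,
                               d0 = d, u0 = u)
  theta <- fit$theta; d <- fit$d; u <- fit$u
  seg <- cumsum(c(1L, as.integer(d != 0)))
  list(theta = theta, segments = seg, state = list(d = d, u = u))
}

# segment-wise Poisson MLE with outliers excluded from the means; also
# returns the leave-self-out rate each position is tested against, so a
# position cannot vouch for its own plausibility
.segment_rates <- function(counts, segments, mask) {
  n <- length(counts)
  rates <- numeric(n)
  loo <- numeric(n)
  fallback <- if (any(mask)) mean(counts[mask]) else mean(counts)
  for (s in unique(segments)) {
    idx <- which(segments == s)
    keep <- idx[mask[idx]]
    seg_sum <- sum(counts[keep]); seg_n <- length(keep)
    rates[idx] <- if (seg_n) seg_sum / seg_n else fallback
    for (i in idx) {
      ni <- seg_n - as.integer(mask[i])
      si <- seg_sum - if (mask[i]) counts[i] else 0
      loo[i] <- if (ni > 0) si / ni else fallback
    }
  }
  list(rates = rates, loo = loo)
}

#' Fit a piecewise-constant Poisson background with outlier detection
#'
#' Fits a first-order trend-filtered Poisson rate to a contiguous window of
#' single-nucleotide counts and flags positions implausible under the local
#' background.  Flagged positions are excluded and the fit repeated until the
#' flag set stabilizes (at most `max_outlier_iter` rounds).
#'
#' @param counts Non-negative integer vector, length >= 3.
#' @param lambda_penalty Positive penalty on adjacent log-rate differences;
#'   `lambda_penalty = 0` returns the unpenalized per-position MLE (the
#'   counts themselves).  `NULL` (default) selects the penalty per window by
#'   halving from an upper bound until the fit shows at least two distinct
#'   levels or a floor is reached.
#' @param outlier_p Poisson upper-tail probability below which a position is
#'   flagged as an outlier (default `1e-6`).
#' @param max_outlier_iter Maximum flag-and-refit rounds (default 20).
#' @return A list with `background_rate` (non-negative numeric vector),
#'   `outlier` (logical vector), `lambda` (penalty used), `segments`
#'   (integer segment ids), and `converged` (flag-set stabilization).
#' @examples
#' fit <- fit_poisson_trend(c(1, 1, 1, 200, 1, 1), lambda_penalty = 5)
#' which(fit$outlier)
#' @export
fit_poisson_trend <- function(counts, lambda_penalty = NULL,
                              outlier_p = 1e-6, max_outlier_iter = 20L) {
  counts <- as.numeric(counts)
  n <- length(counts)
  if (n < 3L) stop("fit_poisson_trend() needs a window of length >= 3")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (all(counts == 0)) {
    return(list(background_rate = numeric(n), outlier = rep(FALSE, n),
                lambda = lambda_penalty %||% 0, segments = rep(1L, n),
                converged = TRUE))
  }
  # initial flags against the global mean rate, so isolated spikes are
  # masked before the segmentation can absorb them into their own level
  p0 <- stats::ppois(counts - 1, mean(counts), lower.tail = FALSE)
  mask <- !(p0 < outlier_p & counts > mean(counts))

  state <- NULL
  if (is.null(lambda_penalty)) {
    # upper bound above which the solution is a single level (Gaussian
    # heuristic on the count scale); halve until >= 2 fitted levels
    lam_max <- max(abs(cumsum(counts - mean(counts))), 1)
    lam <- lam_max
    repeat {
      sol <- .solve_poisson_trend(counts, lam, mask = mask, state = state)
      state <- sol$state
      if (max(sol$segments) >= 2L || lam < lam_max / 1024) break
      lam <- lam / 2
    }
    lambda_penalty <- lam
  }
  if (lambda_penalty < 0) stop("lambda_penalty must be non-negative")

  converged <- FALSE
  segments <- rep(1L, n)
  rates <- rep(mean(counts), n)
  for (round in seq_len(max_outlier_iter)) {
    if (lambda_penalty == 0) {
      segments <- seq_len(n)
    } else {
      sol <- .solve_poisson_trend(counts, lambda_penalty, mask, state = state)
      segments <- sol$segments
      state <- sol$state
    }
    sr <- .segment_rates(counts, segments, mask)
    rates <- sr$rates
    p <- stats::ppois(counts - 1, pmax(sr$loo, 1e-12), lower.tail = FALSE)
    # flags accumulate (once excluded, stays excluded), so the loop is
    # monotone and must stabilize
    new_mask <- mask & !(p < outlier_p & counts > sr$loo)
    if (identical(new_mask, mask)) { converged <- TRUE; break }
    mask <- new_mask
  }
  if (!converged) warning("outlier flag set did not stabilize in ",
                          max_outlier_iter, " rounds; returning last iterate")
  list(background_rate = rates, outlier = !mask, lambda = lambda_penalty,
       segments = segments, converged = converged)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
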