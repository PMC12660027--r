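#' Derivatives-matching gamma approximation of a shape full conditional
#'
#' The full conditional of a gamma shape parameter under a gamma prior and
#' i.i.d. gamma observations (mean parametrization, mean known) has no
#' standard form. Following the derivatives-matching idea, a
#' `Gamma(shape_hat, rate_hat)` density is fitted so that the first and
#' second derivatives of its log density match those of the true
#' (unnormalized) full conditional at the current approximating mean; the
#' matching point is then moved to the fitted mean and the step repeated
#' until it moves less than `tol`.
#'
#' The target is the conditional of `x` under
#' `x ~ Gamma(prior_shape, prior_rate)` with `n` observations
#' `tau_1..tau_n ~ Gamma(s, s / eta)` i.i.d., where the effective shape is
#' `s = 1 + x` when `shift = TRUE` (the shifted-shape reparametrization that
#' keeps `E[1/tau]` finite) and `s = x` otherwise.
#'
#' @param prior_shape,prior_rate gamma prior on the shape parameter
#' @param n number of observations in the cluster (0 returns the prior)
#' @param sum_x,sum_log_x sufficient statistics `sum(tau)` and
#'   `sum(log(tau))`
#' @param eta known component mean of the observations' gamma distribution
#' @param shift use the shifted-shape target (`s = 1 + x`)
#' @param tol convergence tolerance on the matching point
#' @param max_iter maximum number of matching iterations; non-convergence
#'   yields a warning and the last iterate, flagged in the result
#' @return list with `shape`, `rate`, `converged`, `iterations`
#' @export
dm_gamma_shape <- function(prior_shape, prior_rate, n, sum_x, sum_log_x,
                           eta, shift = TRUE, tol = 1e-8, max_iter = 10L,
                           warn = TRUE) {
  stopifnot(prior_shape > 0, prior_rate > 0, n >= 0, tol > 0)
  if (n == 0L) {
    return(list(shape = prior_shape, rate = prior_rate,
                converged = TRUE, iterations = 0L))
  }
  stopifnot(eta > 0)
  gprime <- function(x) {
    s <- if (shift) 1 + x else x
    (prior_shape - 1) / x - prior_rate +
      n * (log(s / eta) + 1) - n * digamma(s) + sum_log_x - sum_x / eta
  }
  gsecond <- function(x) {
    s <- if (shift) 1 + x else x
    -(prior_shape - 1) / x^2 + n / s - n * trigamma(s)
  }
  x <- max(prior_shape / prior_rate, 1e-8)
  A <- prior_shape; B <- prior_rate
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    A <- 1 - x^2 * gsecond(x)
    B <- (A - 1) / x - gprime(x)
    if (!is.finite(A) || !is.finite(B) || A <= 0 || B <= 0) {
      # fall back to a damped step from the previous point
      A <- max(A, 1e-3); B <- max(B, 1e-8)
    }
    x_new <- A / B
    if (!is.finite(x_new) || x_new <= 0) x_new <- x
    # damp large multiplicative jumps to stabilize the fixed point
    x_new <- min(max(x_new, x / 10), x * 10)
    if (abs(x_new - x) < tol * (1 + x)) {
      x <- x_new
      converged <- TRUE
      break
    }
    x <- x_new
  }
  if (!converged && warn) {
    warning("derivatives-matching did not converge within ", max_iter,
            " iterations (last point ", signif(x, 6), ")")
  }
  list(shape = A, rate = B, converged = converged, iterations = it)
}

# Unnormalized log full conditional of the gamma shape (test / oracle use).
dm_log_target <- function(x, prior_shape, prior_rate, n, sum_x, sum_log_x,
                          eta, shift = TRUE) {
  s <- if (shift) 1 + x else x
  (prior_shape - 1) * log(x) - prior_rate * x +
    n * (s * log(s / eta)) - n * lgamma(s) +
    (s - 1) * sum_log_x - (s / eta) * sum_x
}
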