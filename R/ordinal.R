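# Coarsened / ordinal ratings via the underlying-variable (heteroscedastic
# ordered probit) formulation: an unobserved continuous rating y* generates
# the observed category through shared ordered thresholds.

#' Ordered-probit cell probability
#'
#' Probability that the observed category equals `category` given the
#' latent mean `theta + b` and rater precision `tau`:
#' `Phi((zeta_c - mean)/sd) - Phi((zeta_{c-1} - mean)/sd)` with
#' `sd = tau^(-1/2)` and `zeta_0 = -Inf`, `zeta_C = +Inf`.
#'
#' @param category integer category in `1..C` (vectorised)
#' @param theta,b,tau subject true score, rater bias, rater precision
#'   (vectorised, `tau > 0`)
#' @param zeta interior thresholds `zeta_1 < ... < zeta_{C-1}`
#' @return vector of probabilities
#' @export
cell_probability <- function(category, theta, b, tau, zeta) {
  stopifnot(all(tau > 0), !is.unsorted(zeta))
  C <- length(zeta) + 1L
  stopifnot(all(category >= 1L), all(category <= C))
  zl <- c(-Inf, zeta)[category]
  zu <- c(zeta, Inf)[category]
  mean_ <- theta + b
  sd_ <- 1 / sqrt(tau)
  pnorm(zu, mean_, sd_) - pnorm(zl, mean_, sd_)
}

#' Augment a latent rating for an observed category
#'
#' Draws from `N(mean, sd^2)` truncated to the category's threshold
#' interval `(zeta_{c-1}, zeta_c]`.
#'
#' @param category observed categories (vectorised)
#' @param mean,sd latent normal parameters
#' @param zeta interior thresholds
#' @return latent values, one per observation
#' @export
augment_latent <- function(category, mean, sd, zeta) {
  stopifnot(!is.unsorted(zeta))
  C <- length(zeta) + 1L
  stopifnot(all(category >= 1L), all(category <= C))
  zl <- c(-Inf, zeta)[category]
  zu <- c(zeta, Inf)[category]
  if (any(zl > zu)) stop("empty threshold interval")
  rtruncnorm(length(category), mean, sd, zl, zu)
}

#' Update free thresholds given latent ratings
#'
#' Each free threshold `zeta_c` is uniform between the largest latent value
#' observed in category `c` and the smallest latent value in category
#' `c + 1`, clipped to the adjacent thresholds; with no observations in a
#' category the corresponding bound falls back to the adjacent threshold.
#'
#' @param ystar latent ratings
#' @param category observed categories
#' @param zeta current interior thresholds
#' @param fixed logical mask: `TRUE` thresholds are left untouched
#' @return updated threshold vector
#' @export
update_thresholds <- function(ystar, category, zeta, fixed) {
  C <- length(zeta) + 1L
  stopifnot(length(fixed) == C - 1L)
  for (cc in which(!fixed)) {
    lo_adj <- if (cc == 1L) -Inf else zeta[cc - 1L]
    hi_adj <- if (cc == C - 1L) Inf else zeta[cc + 1L]
    in_c <- ystar[category == cc]
    in_c1 <- ystar[category == cc + 1L]
    lo <- if (length(in_c)) max(lo_adj, max(in_c)) else lo_adj
    hi <- if (length(in_c1)) min(hi_adj, min(in_c1)) else hi_adj
    if (!is.finite(lo) || !is.finite(hi)) {
      # vacuous constraint at an open end: keep the current value
      next
    }
    if (hi < lo) stop("inconsistent latent ordering at threshold ", cc)
    zeta[cc] <- runif(1L, lo, hi)
  }
  zeta
}

# One full sweep of the ordinal sampler: augmentation, continuous kernel on
# the latent ratings, threshold update. C = 2 fixes all rater precisions at
# 1 (raters assumed equally reliable).
.sweep_ordinal <- function(state, d, cfg) {
  fix_tau <- cfg$n_categories == 2L
  mean_ <- state$theta[d$si] + state$b[d$ri]
  sd_ <- 1 / sqrt(state$tau[d$ri])
  state$ystar <- augment_latent(d$y, mean_, sd_, state$zeta)
  state <- .sweep_twoway(state, state$ystar, d, cfg, fix_tau = fix_tau)
  if (fix_tau) state$tau <- rep(1, d$J)
  state$zeta <- update_thresholds(state$ystar, d$y, state$zeta,
                                  cfg$thresholds_fixed)
  state
}
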