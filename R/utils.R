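#' @importFrom stats dnorm pnorm qnorm rnorm rgamma rbeta runif rbinom
#'   quantile var sd median density hclust cutree as.dist dist setNames
#'   rmultinom aggregate
#' @importFrom utils head tail
NULL

# Numerical floor applied to all variances in the sampler.
.VAR_FLOOR <- 1e-10

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Draw from a truncated normal distribution
#'
#' Inverse-CDF sampler for `N(mean, sd^2)` truncated to `(lower, upper]`.
#' Used by the ordinal-data augmentation step; accurate enough for the
#' moderate tail regions encountered there, with a clamp guarding the
#' extreme-tail case where both CDF values collapse numerically.
#'
#' @param n number of draws
#' @param mean,sd normal parameters (vectorised)
#' @param lower,upper truncation bounds, may be `-Inf`/`Inf`
#' @return numeric vector of `n` draws
#' @export
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  bad <- pu <= pl
  u <- runif(n, pmin(pl, pu), pu)
  x <- qnorm(u, mean, sd)
  # collapse region: both tails underflow -> return nearest finite bound
  if (any(bad)) {
    lo <- rep_len(lower, n); up <- rep_len(upper, n)
    m <- rep_len(mean, n)
    x[bad] <- ifelse(is.finite(lo[bad]) & is.finite(up[bad]),
                     (lo[bad] + up[bad]) / 2,
                     ifelse(is.finite(lo[bad]), lo[bad],
                            ifelse(is.finite(up[bad]), up[bad], m[bad])))
  }
  # keep draws strictly inside the interval despite qnorm rounding
  lo <- rep_len(lower, n); up <- rep_len(upper, n)
  pmin(pmax(x, ifelse(is.finite(lo), lo, -Inf)), ifelse(is.finite(up), up, Inf))
}

# Mean of N(mean, sd^2) truncated to (a, b]; closed form.
truncnorm_mean <- function(mean, sd, a, b) {
  al <- (a - mean) / sd
  be <- (b - mean) / sd
  z <- pnorm(be) - pnorm(al)
  mean + sd * (dnorm(al) - dnorm(be)) / z
}

#' Draw from a skew-normal distribution
#'
#' Standard (location, scale, slant) construction: with
#' `delta = slant / sqrt(1 + slant^2)`,
#' `X = location + scale * (delta * |U0| + sqrt(1 - delta^2) * U1)`
#' for independent standard normals `U0`, `U1`.
#'
#' @param n number of draws
#' @param location,scale,slant skew-normal parameters; `scale > 0`
#' @return numeric vector
#' @export
rskewnorm <- function(n, location = 0, scale = 1, slant = 0) {
  stopifnot(all(scale > 0))
  delta <- slant / sqrt(1 + slant^2)
  u0 <- abs(rnorm(n))
  u1 <- rnorm(n)
  location + scale * (delta * u0 + sqrt(1 - delta^2) * u1)
}

# Closed-form mean/variance/skewness of the skew-normal.
skewnorm_moments <- function(location, scale, slant) {
  delta <- slant / sqrt(1 + slant^2)
  mu <- location + scale * delta * sqrt(2 / pi)
  v <- scale^2 * (1 - 2 * delta^2 / pi)
  g <- (4 - pi) / 2 * (delta * sqrt(2 / pi))^3 / (1 - 2 * delta^2 / pi)^1.5
  list(mean = mu, var = v, skewness = g)
}

# log-sum-exp over rows of a matrix, returning normalized probabilities.
softmax_rows <- function(logp) {
  m <- apply(logp, 1L, max)
  w <- exp(logp - m)
  w / rowSums(w)
}

# Vectorised categorical draw: one draw per row of a probability matrix.
sample_categorical_rows <- function(prob) {
  cum <- t(apply(prob, 1L, cumsum))
  u <- runif(nrow(prob)) * cum[, ncol(cum)]
  max.col(u <= cum, ties.method = "first")
}

# Group sums of x by integer index f in 1..nlev (zero for empty groups).
group_sum <- function(x, f, nlev) {
  out <- numeric(nlev)
  s <- rowsum(x, f)
  out[as.integer(rownames(s))] <- s
  out
}

group_count <- function(f, nlev) {
  tabulate(f, nbins = nlev)
}
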