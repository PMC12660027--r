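#' Stick-breaking weights from Beta fractions
#'
#' Truncated stick-breaking construction: `p_r = v_r * prod_{s<r}(1 - v_s)`
#' with the final fraction forced to one so the weights sum to one exactly.
#' A renormalization guard removes any residual floating-point drift.
#'
#' @param v fractions in `[0, 1]`; the last element is forced to 1
#' @return numeric vector of weights summing to 1
#' @examples
#' stick_weights(c(0.5, 0.5, 1))  # 0.5, 0.25, 0.25
#' @export
stick_weights <- function(v) {
  v <- as.numeric(v)
  if (any(v < 0 | v > 1)) stop("stick fractions must lie in [0, 1]")
  R <- length(v)
  v[R] <- 1
  log1mv <- log1p(-v[-R])
  p <- v * c(1, exp(cumsum(log1mv)))
  p[!is.finite(p)] <- 0
  p / sum(p)
}

#' Moments of a finite normal mixture
#'
#' Mean and variance of a mixture of normal components by the law of total
#' variance: `mean = sum(w * mu)`,
#' `var = sum(w * (sigma2 + mu^2)) - mean^2`. Used for the subject
#' true-score mixture and (with bias atoms) the rater-bias mixture.
#'
#' @param w mixture weights summing to one
#' @param mu component means
#' @param sigma2 component variances
#' @return named numeric vector `c(mean, var)`
#' @export
mixture_moments <- function(w, mu, sigma2) {
  stopifnot(length(w) == length(mu), length(mu) == length(sigma2),
            all(sigma2 >= 0))
  m <- sum(w * mu)
  v <- sum(w * (sigma2 + mu^2)) - m^2
  c(mean = m, var = max(v, 0))
}

#' Subject true-score mixture moments
#'
#' @param w stick-breaking weights
#' @param atoms data frame / list with components `mu` (locations) and
#'   `sigma2` (variances) of the subject mixture
#' @return named vector `c(mean_theta, var_theta)`
#' @export
subject_moments <- function(w, atoms) {
  m <- mixture_moments(w, atoms$mu, atoms$sigma2)
  c(mean_theta = unname(m["mean"]), var_theta = unname(m["var"]))
}

#' Rater systematic-bias mixture moments
#'
#' @param w stick-breaking weights
#' @param atoms list with components `beta` (bias means) and `omega2`
#'   (bias variances)
#' @return named vector `c(mean_b, var_b)`
#' @export
rater_bias_moments <- function(w, atoms) {
  m <- mixture_moments(w, atoms$beta, atoms$omega2)
  c(mean_b = unname(m["mean"]), var_b = unname(m["var"]))
}

#' Rater reliability mixture moments and mean residual variance
#'
#' Reliability (precision) within component `k` follows a gamma distribution
#' with shifted shape `1 + nu_k` and mean `eta_k`, so its inverse (the
#' residual variance) has a finite mean
#' `E[1/tau | k] = (1 + nu_k) / (nu_k * eta_k)` for every `nu_k > 0`.
#' The gamma-mixture mean/variance of tau and the mixture mean of `1/tau`
#' are returned; the latter is the `mean_residual_var` entering the
#' population ICC lower bound.
#'
#' @param w stick-breaking weights
#' @param atoms list with components `nu` (> 0, pre-shift gamma shapes) and
#'   `eta` (> 0, reliability means)
#' @param shifted if `TRUE` (default) the component shape is `1 + nu`,
#'   guaranteeing `E[1/tau]` exists; if `FALSE` the raw shape `nu` is used
#'   and any component with `nu <= 1` is an error.
#' @return named vector `c(mean_tau, var_tau, mean_residual_var)`
#' @export
reliability_moments <- function(w, atoms, shifted = TRUE) {
  nu <- atoms$nu; eta <- atoms$eta
  stopifnot(all(nu > 0), all(eta > 0), length(w) == length(nu))
  shape <- if (shifted) 1 + nu else nu
  if (any(shape <= 1)) {
    stop("component shape <= 1: mean residual variance undefined; ",
         "use the shifted-shape reparametrization (shifted = TRUE)")
  }
  # component variance of Gamma(shape, mean eta): eta^2 / shape
  m <- sum(w * eta)
  v <- sum(w * (eta^2 / shape + eta^2)) - m^2
  inv_mean <- sum(w * shape / (eta * (shape - 1)))
  c(mean_tau = m, var_tau = max(v, 0), mean_residual_var = inv_mean)
}

#' Draw mixture atoms from a base measure
#'
#' Draws `n` independent atoms from the subject base measure
#' (`mu ~ N(m_mu, s2_mu)`, precision `1/sigma2 ~ Gamma(a_prec, mean
#' m_prec)`) or the rater base measure (`beta ~ N(m_beta, s2_beta)`,
#' precision `1/omega2 ~ Gamma(a_om, mean m_om)`,
#' `nu ~ Gamma(a_nu, mean m_nu)`, `eta ~ Inv-Gamma(c_eta, scale d_eta)`).
#' Used to refresh empty clusters in the blocked Gibbs sweep.
#'
#' @param which `"subject"` or `"rater"`
#' @param params base-measure parameter list; see [default_base_params()]
#' @param n number of atoms
#' @return a list of atom vectors (`mu`, `sigma2` or `beta`, `omega2`,
#'   `nu`, `eta`), each of length `n`
#' @export
draw_from_base <- function(which = c("subject", "rater"), params, n) {
  which <- match.arg(which)
  if (n == 0L) {
    return(if (which == "subject") list(mu = numeric(0), sigma2 = numeric(0))
           else list(beta = numeric(0), omega2 = numeric(0),
                     nu = numeric(0), eta = numeric(0)))
  }
  if (which == "subject") {
    mu <- rnorm(n, params$m_mu, sqrt(params$s2_mu))
    prec <- rgamma(n, shape = params$a_prec,
                   rate = params$a_prec / params$m_prec)
    list(mu = mu, sigma2 = pmax(1 / prec, .VAR_FLOOR))
  } else {
    beta <- rnorm(n, params$m_beta, sqrt(params$s2_beta))
    prec <- rgamma(n, shape = params$a_om, rate = params$a_om / params$m_om)
    nu <- rgamma(n, shape = params$a_nu, rate = params$a_nu / params$m_nu)
    eta <- params$d_eta / rgamma(n, shape = params$c_eta, rate = 1)
    list(beta = beta, omega2 = pmax(1 / prec, .VAR_FLOOR),
         nu = pmax(nu, 1e-8), eta = pmax(eta, .VAR_FLOOR))
  }
}

#' Default base-measure parameters
#'
#' Initial values of the base-measure parameters before any hyperparameter
#' updating; the subject location prior is centered at the rating scale's
#' center value.
#'
#' @param center rating-scale center, `(L + U) / 2`
#' @param spread prior variance of the location components
#' @return named list of subject (`m_mu`, `s2_mu`, `a_prec`, `m_prec`) and
#'   rater (`m_beta`, `s2_beta`, `a_om`, `m_om`, `a_nu`, `m_nu`, `c_eta`,
#'   `d_eta`) base parameters
#' @export
default_base_params <- function(center, spread = (center / 2)^2) {
  list(
    # subject: mu ~ N(m_mu, s2_mu); 1/sigma2 ~ Gamma(a_prec, mean m_prec)
    m_mu = center, s2_mu = spread, a_prec = 2, m_prec = 1 / (center / 5)^2,
    # rater: beta ~ N(m_beta, s2_beta); 1/omega2 ~ Gamma(a_om, mean m_om)
    m_beta = 0, s2_beta = spread / 4, a_om = 2, m_om = 1 / (center / 10)^2,
    # reliability atoms: nu ~ Gamma(a_nu, mean m_nu); eta ~ InvGamma(c_eta, d_eta)
    a_nu = 2, m_nu = 2, c_eta = 2, d_eta = 0.5)
}
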