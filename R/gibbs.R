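#' Model configuration for rating-model fits
#'
#' Collects the model variant, design, likelihood, truncation levels, MCMC
#' controls and hyperprior constants. The `BP` variant forces both
#' truncations to 1 (every subject and rater in one cluster); `BSP` forces
#' the rater truncation to 1 while the subject mixture stays nonparametric.
#'
#' @param variant `"BNP"`, `"BSP"` or `"BP"`
#' @param design `"two_way"` (rater identity modeled) or `"one_way"`
#'   (per-rating error mixture, rater identity ignored)
#' @param likelihood `"continuous"` or `"ordinal"`
#' @param R_subj,R_rater truncation levels of the subject and rater
#'   stick-breaking mixtures
#' @param iterations,burnin,thin MCMC controls; `iterations > burnin`,
#'   `thin >= 1`. Defaults mirror a production run (80,000 iterations,
#'   20,000 burn-in, thinning 60); desk-scale analyses pass smaller values.
#' @param seed integer seed driving all randomness of the fit
#' @param scale_low,scale_high rating-scale bounds (continuous likelihood)
#' @param n_categories number of ordered categories (ordinal likelihood)
#' @param thresholds numeric vector of `n_categories - 1` initial interior
#'   thresholds (ordinal); `NULL` uses equally spaced standardized values
#' @param thresholds_fixed logical mask over interior thresholds; by default
#'   the first and last are fixed (two fixed interior thresholds are
#'   required for identifiability when `n_categories >= 3`)
#' @param grid_bounds,grid_n density-grid specification for posterior
#'   density summaries
#' @param update_hyper update base-measure hyperparameters (default `TRUE`)
#' @param hyper named list overriding hyperprior constants; see Details
#' @details Hyperprior constants (overridable through `hyper`): `prec0_loc`
#'   (prior precision of the base-measure location means, default 0.005),
#'   `a0`/`b0` (vague gamma/inverse-gamma hyperprior constants, default
#'   0.005), `base_shape` (fixed gamma shape of the precision- and
#'   shape-type base components, default 3, which keeps empty-cluster
#'   refresh draws heavy-tail-free while their means are learned),
#'   `m_nu0` (fixed mean of the reliability-shape base component,
#'   default 3; this scale is only weakly identified and is deliberately
#'   not given a hyperprior), `alpha_a`/`alpha_b` (gamma hyperprior of both DP concentrations,
#'   default 1 and 1), `c_eta` (fixed inverse-gamma shape of the
#'   reliability-mean base component, default 3), `dm_tol` and
#'   `dm_max_iter` (derivatives-matching controls, defaults `1e-8` and 10).
#' @return a list of class `rater_config`
#' @export
rater_config <- function(variant = c("BNP", "BSP", "BP"),
                         design = c("two_way", "one_way"),
                         likelihood = c("continuous", "ordinal"),
                         R_subj = 30L, R_rater = 20L,
                         iterations = 80000L, burnin = 20000L, thin = 60L,
                         seed = 1L,
                         scale_low = 1, scale_high = 100,
                         n_categories = NULL,
                         thresholds = NULL, thresholds_fixed = NULL,
                         grid_bounds = NULL, grid_n = 128L,
                         update_hyper = TRUE,
                         hyper = list()) {
  variant <- match.arg(variant)
  design <- match.arg(design)
  likelihood <- match.arg(likelihood)
  if (variant == "BP") { R_subj <- 1L; R_rater <- 1L }
  if (variant == "BSP") R_rater <- 1L
  stopifnot(iterations > burnin, thin >= 1, R_subj >= 1, R_rater >= 1)
  h <- list(prec0_loc = 0.005, a0 = 0.005, b0 = 0.005,
            base_shape = 3, m_nu0 = 3, alpha_a = 1, alpha_b = 1,
            c_eta = 3, dm_tol = 1e-8, dm_max_iter = 10L)
  h[names(hyper)] <- hyper
  if (likelihood == "ordinal") {
    stopifnot(!is.null(n_categories), n_categories >= 2)
    C <- as.integer(n_categories)
    if (is.null(thresholds)) thresholds <- seq(-1, 1, length.out = C - 1L)
    stopifnot(length(thresholds) == C - 1L,
              !is.unsorted(thresholds, strictly = (C > 2L)))
    if (is.null(thresholds_fixed)) {
      thresholds_fixed <- rep(FALSE, C - 1L)
      thresholds_fixed[c(1L, C - 1L)] <- TRUE
    }
    if (C >= 3L && sum(thresholds_fixed) < 2L) {
      stop("at least two interior thresholds must be fixed when C >= 3")
    }
  }
  structure(list(variant = variant, design = design,
                 likelihood = likelihood,
                 R_subj = as.integer(R_subj), R_rater = as.integer(R_rater),
                 iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = as.integer(seed),
                 scale_low = scale_low, scale_high = scale_high,
                 n_categories = if (likelihood == "ordinal")
                   as.integer(n_categories) else NULL,
                 thresholds = thresholds,
                 thresholds_fixed = thresholds_fixed,
                 grid_bounds = grid_bounds, grid_n = as.integer(grid_n),
                 update_hyper = isTRUE(update_hyper), hyper = h),
            class = "rater_config")
}

.scale_center <- function(cfg) {
  if (cfg$likelihood == "ordinal") 0 else (cfg$scale_low + cfg$scale_high) / 2
}

# Internal record view of a ratings table.
.dat_view <- function(data) {
  list(si = data$subject_idx, ri = data$rater_idx,
       y = as.numeric(data$rating),
       I = length(attr(data, "subjects")),
       J = length(attr(data, "raters")),
       N = nrow(data))
}

#' Initialize the sampler state
#'
#' Subjects start at their mean observed rating, raters at their mean
#' residual, reliabilities at the pooled residual precision; allocations by
#' quantile binning of the initial values into at most five occupied
#' clusters with atoms at within-bin moments and uniform weights over the
#' occupied sticks.
#'
#' @param data a [ratings()] table
#' @param cfg a [rater_config()]
#' @return an `MCMCState` list
#' @export
init_state <- function(data, cfg) {
  d <- .dat_view(data)
  if (any(tabulate(d$si, d$I) == 0L)) stop("subject with zero ratings")
  y <- d$y
  if (cfg$likelihood == "ordinal") {
    # crude latent init: midpoint of each category's threshold interval
    zeta <- cfg$thresholds
    mids <- .category_midpoints(zeta)
    y <- mids[d$y]
  }
  center <- .scale_center(cfg)
  theta <- as.numeric(group_sum(y, d$si, d$I) / tabulate(d$si, d$I))
  resid1 <- y - theta[d$si]
  nj <- tabulate(d$ri, d$J)
  b <- as.numeric(group_sum(resid1, d$ri, d$J) / pmax(nj, 1L))
  resid2 <- resid1 - b[d$ri]
  pooled <- max(var(resid2), .VAR_FLOOR)
  tau <- rep(1 / pooled, d$J)

  base <- default_base_params(max(abs(center), 1))
  base$m_mu <- center
  base$m_beta <- 0
  base$a_prec <- base$a_om <- base$a_nu <- cfg$hyper$base_shape
  base$m_nu <- cfg$hyper$m_nu0
  base$c_eta <- cfg$hyper$c_eta

  bin_alloc <- function(x, R) {
    K <- min(5L, R)
    if (K == 1L) return(rep(1L, length(x)))
    qs <- quantile(x, probs = seq(0, 1, length.out = K + 1L), names = FALSE)
    qs[1L] <- -Inf; qs[K + 1L] <- Inf
    as.integer(cut(x, breaks = unique(qs), include.lowest = TRUE))
  }
  cA <- bin_alloc(theta, cfg$R_subj)
  zA <- bin_alloc(b, cfg$R_rater)

  bin_moments <- function(x, f, R, fallback_var) {
    mu <- numeric(R); s2 <- rep(fallback_var, R)
    for (r in seq_len(R)) {
      xs <- x[f == r]
      if (length(xs)) {
        mu[r] <- mean(xs)
        if (length(xs) > 1L) s2[r] <- max(var(xs), .VAR_FLOOR)
      } else {
        mu[r] <- mean(x)
      }
    }
    list(mu = mu, s2 = s2)
  }
  sm <- bin_moments(theta, cA, cfg$R_subj, max(var(theta), 1))
  rm_ <- bin_moments(b, zA, cfg$R_rater, max(var(b), 0.5))

  occ_w <- function(f, R) {
    w <- tabulate(f, R)
    w <- ifelse(w > 0, 1, 0.01)
    w / sum(w)
  }
  state <- list(
    theta = theta, b = b, tau = tau,
    c = cA, z = zA,
    sub_atoms = list(mu = sm$mu, sigma2 = sm$s2),
    rat_atoms = list(beta = rm_$mu, omega2 = rm_$s2,
                     nu = rep(2, cfg$R_rater),
                     eta = rep(1 / pooled, cfg$R_rater)),
    p = occ_w(cA, cfg$R_subj), v = rep(0.5, cfg$R_subj),
    q = occ_w(zA, cfg$R_rater), u = rep(0.5, cfg$R_rater),
    alpha_G = 1, alpha_H = 1,
    base = base,
    dm_failures = 0L)
  if (cfg$likelihood == "ordinal") {
    state$zeta <- cfg$thresholds
    state$ystar <- y
    if (cfg$n_categories == 2L) state$tau <- rep(1, d$J)
  }
  state
}

.category_midpoints <- function(zeta) {
  C <- length(zeta) + 1L
  lo <- c(zeta[1L] - 1, zeta)
  hi <- c(zeta, zeta[C - 1L] + 1)
  (lo + hi) / 2
}

# ---- conditional updates (two-way continuous kernel) ----------------------

.update_theta <- function(state, y, d) {
  tau_r <- state$tau[d$ri]
  prec_lik <- group_sum(tau_r, d$si, d$I)
  num_lik <- group_sum(tau_r * (y - state$b[d$ri]), d$si, d$I)
  mu_c <- state$sub_atoms$mu[state$c]
  s2_c <- state$sub_atoms$sigma2[state$c]
  post_prec <- 1 / s2_c + prec_lik
  post_mean <- (mu_c / s2_c + num_lik) / post_prec
  state$theta <- rnorm(d$I, post_mean, sqrt(1 / post_prec))
  state
}

.update_subject_alloc <- function(state, d, R) {
  if (R == 1L) { state$c <- rep(1L, d$I); return(state) }
  logp <- matrix(log(pmax(state$p, 1e-300)), d$I, R, byrow = TRUE) +
    dnorm(matrix(state$theta, d$I, R),
          matrix(state$sub_atoms$mu, d$I, R, byrow = TRUE),
          matrix(sqrt(state$sub_atoms$sigma2), d$I, R, byrow = TRUE),
          log = TRUE)
  state$c <- sample_categorical_rows(softmax_rows(logp))
  state
}

.update_subject_atoms <- function(state, d, cfg) {
  R <- cfg$R_subj
  bp <- state$base
  nn <- group_count(state$c, R)
  S <- group_sum(state$theta, state$c, R)
  # location given current scale
  post_prec <- 1 / bp$s2_mu + nn / state$sub_atoms$sigma2
  post_mean <- (bp$m_mu / bp$s2_mu + S / state$sub_atoms$sigma2) / post_prec
  mu <- rnorm(R, post_mean, sqrt(1 / post_prec))
  # scale (precision) given new location
  SS <- group_sum((state$theta - mu[state$c])^2, state$c, R)
  lam <- rgamma(R, shape = bp$a_prec + nn / 2,
                rate = bp$a_prec / bp$m_prec + SS / 2)
  sigma2 <- pmax(1 / lam, .VAR_FLOOR)
  # refresh empty clusters from the base measure
  empty <- nn == 0L
  if (any(empty)) {
    fresh <- draw_from_base("subject", bp, sum(empty))
    mu[empty] <- fresh$mu
    sigma2[empty] <- fresh$sigma2
  }
  state$sub_atoms <- list(mu = mu, sigma2 = sigma2)
  state
}

# Stick-fraction update v_r ~ Beta(1 + n_r, alpha + n_{>r}). The fractions
# are drawn through their underlying gammas so that log(1 - v_r) is exact
# even when v_r is numerically 1 (tiny second shape); the concentration
# update needs that quantity unclamped to stay unbiased.
.update_sticks <- function(counts, alpha) {
  R <- length(counts)
  if (R == 1L) return(list(v = 1, p = 1, log1mv = 0))
  ngt <- rev(cumsum(rev(counts))) - counts
  a <- (1 + counts)[-R]
  b <- (alpha + ngt)[-R]
  logG1 <- log(rgamma(R - 1L, shape = a, rate = 1))
  # log of a Gamma(b) draw, stable for small shapes:
  # G ~ Gamma(b)  <=>  G = X * U^(1/b) with X ~ Gamma(b + 1), U ~ Unif(0,1)
  small <- b < 0.1
  logG2 <- numeric(R - 1L)
  if (any(!small)) {
    logG2[!small] <- log(rgamma(sum(!small), shape = b[!small], rate = 1))
  }
  if (any(small)) {
    logG2[small] <- log(rgamma(sum(small), shape = b[small] + 1, rate = 1)) +
      log(runif(sum(small))) / b[small]
  }
  m <- pmax(logG1, logG2)
  lse <- m + log(exp(logG1 - m) + exp(logG2 - m))
  log1mv <- c(logG2 - lse, -Inf)           # log(1 - v_r); v_R = 1
  v <- c(exp(logG1 - lse), 1)
  # weights straight from the logs: p_r = v_r * prod_{s<r} (1 - v_s)
  p <- v * c(1, exp(cumsum(log1mv[-R])))
  p[!is.finite(p)] <- 0
  s <- sum(p)
  if (s <= 0) { p <- rep(0, R); p[1L] <- 1 } else p <- p / s
  list(v = v, p = p, log1mv = log1mv)
}

.update_rater_effects <- function(state, y, d, fix_tau = FALSE) {
  resid <- y - state$theta[d$si]
  nj <- tabulate(d$ri, d$J)
  Sj <- group_sum(resid, d$ri, d$J)
  beta_z <- state$rat_atoms$beta[state$z]
  om2_z <- state$rat_atoms$omega2[state$z]
  post_prec <- 1 / om2_z + nj * state$tau
  post_mean <- (beta_z / om2_z + state$tau * Sj) / post_prec
  state$b <- rnorm(d$J, post_mean, sqrt(1 / post_prec))
  if (!fix_tau) {
    SSj <- group_sum((resid - state$b[d$ri])^2, d$ri, d$J)
    s_z <- 1 + state$rat_atoms$nu[state$z]
    eta_z <- state$rat_atoms$eta[state$z]
    state$tau <- rgamma(d$J, shape = s_z + nj / 2,
                        rate = s_z / eta_z + SSj / 2)
    state$tau <- pmax(state$tau, 1e-12)
  }
  state
}

.update_rater_alloc <- function(state, d, R, fix_tau = FALSE) {
  if (R == 1L) { state$z <- rep(1L, d$J); return(state) }
  A <- state$rat_atoms
  logp <- matrix(log(pmax(state$q, 1e-300)), d$J, R, byrow = TRUE) +
    dnorm(matrix(state$b, d$J, R),
          matrix(A$beta, d$J, R, byrow = TRUE),
          matrix(sqrt(A$omega2), d$J, R, byrow = TRUE), log = TRUE)
  if (!fix_tau) {
    sh <- matrix(1 + A$nu, d$J, R, byrow = TRUE)
    rt <- sh / matrix(A$eta, d$J, R, byrow = TRUE)
    logp <- logp + stats::dgamma(matrix(state$tau, d$J, R), shape = sh,
                                 rate = rt, log = TRUE)
  }
  state$z <- sample_categorical_rows(softmax_rows(logp))
  state
}

.update_rater_atoms <- function(state, cfg, fix_tau = FALSE) {
  R <- cfg$R_rater
  bp <- state$base
  h <- cfg$hyper
  nk <- group_count(state$z, R)
  Sb <- group_sum(state$b, state$z, R)
  A <- state$rat_atoms
  # bias location
  post_prec <- 1 / bp$s2_beta + nk / A$omega2
  post_mean <- (bp$m_beta / bp$s2_beta + Sb / A$omega2) / post_prec
  beta <- rnorm(R, post_mean, sqrt(1 / post_prec))
  # bias scale (precision)
  SSb <- group_sum((state$b - beta[state$z])^2, state$z, R)
  kap <- rgamma(R, shape = bp$a_om + nk / 2,
                rate = bp$a_om / bp$m_om + SSb / 2)
  omega2 <- pmax(1 / kap, .VAR_FLOOR)
  nu <- A$nu; eta <- A$eta
  if (!fix_tau) {
    Ts <- group_sum(state$tau, state$z, R)
    Tl <- group_sum(log(state$tau), state$z, R)
    for (k in which(nk > 0L)) {
      fit <- dm_gamma_shape(bp$a_nu, bp$a_nu / bp$m_nu, nk[k], Ts[k], Tl[k],
                            eta[k], shift = TRUE,
                            tol = h$dm_tol, max_iter = h$dm_max_iter,
                            warn = FALSE)
      if (!fit$converged) state$dm_failures <- state$dm_failures + 1L
      nu[k] <- max(rgamma(1L, shape = fit$shape, rate = fit$rate), 1e-8)
      # reliability mean: inverse-gamma conjugate given shifted shape
      s <- 1 + nu[k]
      g <- rgamma(1L, shape = bp$c_eta + s * nk[k], rate = 1)
      eta[k] <- max((bp$d_eta + s * Ts[k]) / g, .VAR_FLOOR)
    }
  }
  empty <- nk == 0L
  if (any(empty)) {
    fresh <- draw_from_base("rater", bp, sum(empty))
    beta[empty] <- fresh$beta
    omega2[empty] <- fresh$omega2
    if (!fix_tau) {
      nu[empty] <- fresh$nu
      eta[empty] <- fresh$eta
    }
  }
  state$rat_atoms <- list(beta = beta, omega2 = omega2, nu = nu, eta = eta)
  state
}

.update_concentration <- function(log1mv, a, b) {
  R <- length(log1mv)
  if (R == 1L) return(rgamma(1L, shape = a, rate = b))
  s <- -sum(log1mv[-R])
  rgamma(1L, shape = a + R - 1, rate = b + s)
}

.update_base_params <- function(state, cfg, rater_block = TRUE) {
  h <- cfg$hyper
  bp <- state$base
  center <- bp$center %||% .scale_center(cfg)
  # subject normal part
  mu <- state$sub_atoms$mu
  R <- length(mu)
  pp <- h$prec0_loc + R / bp$s2_mu
  pm <- (h$prec0_loc * center + sum(mu) / bp$s2_mu) / pp
  bp$m_mu <- rnorm(1L, pm, sqrt(1 / pp))
  prec_mu <- rgamma(1L, shape = h$a0 + R / 2,
                    rate = h$b0 + sum((mu - bp$m_mu)^2) / 2)
  bp$s2_mu <- min(max(1 / prec_mu, .VAR_FLOOR), 1e10)
  # subject scale part: lambda_n ~ Gamma(a_prec, mean m_prec); the mean has
  # a conjugate inverse-gamma conditional given the fixed shape
  lam <- 1 / state$sub_atoms$sigma2
  g <- rgamma(1L, shape = h$a0 + bp$a_prec * R, rate = 1)
  bp$m_prec <- max((h$b0 + bp$a_prec * sum(lam)) / g, 1e-12)
  if (rater_block) {
    A <- state$rat_atoms
    K <- length(A$beta)
    pp <- h$prec0_loc + K / bp$s2_beta
    pm <- (sum(A$beta) / bp$s2_beta) / pp   # prior centered at 0
    bp$m_beta <- rnorm(1L, pm, sqrt(1 / pp))
    prec_b <- rgamma(1L, shape = h$a0 + K / 2,
                     rate = h$b0 + sum((A$beta - bp$m_beta)^2) / 2)
    bp$s2_beta <- min(max(1 / prec_b, .VAR_FLOOR), 1e10)
    kap <- 1 / A$omega2
    g <- rgamma(1L, shape = h$a0 + bp$a_om * K, rate = 1)
    bp$m_om <- max((h$b0 + bp$a_om * sum(kap)) / g, 1e-12)
    # m_nu stays fixed: the reliability-shape scale is only weakly
    # identified and letting it track the atoms creates an absorbing
    # degenerate regime (nu -> Inf, reliabilities collapsing on eta)
    bp$d_eta <- rgamma(1L, shape = h$a0 + bp$c_eta * K,
                       rate = h$b0 + sum(1 / A$eta))
    bp$d_eta <- max(bp$d_eta, 1e-12)
  }
  state$base <- bp
  state
}

#' One blocked Gibbs sweep of the two-way model
#'
#' Updates, in order: subject true scores, subject allocations, subject
#' atoms, subject stick fractions, rater biases and reliabilities, rater
#' allocations, rater atoms (gamma shapes through the derivatives-matching
#' approximation), rater sticks, both concentration parameters, and the
#' base-measure hyperparameters.
#'
#' @param state an `MCMCState` from [init_state()] or a previous sweep
#' @param data a [ratings()] table (continuous)
#' @param cfg a [rater_config()]
#' @return the updated state
#' @export
gibbs_sweep <- function(state, data, cfg) {
  d <- .dat_view(data)
  .sweep_twoway(state, d$y, d, cfg)
}

.sweep_twoway <- function(state, y, d, cfg, fix_tau = FALSE) {
  state <- .update_theta(state, y, d)
  state <- .update_subject_alloc(state, d, cfg$R_subj)
  state <- .update_subject_atoms(state, d, cfg)
  st <- .update_sticks(group_count(state$c, cfg$R_subj), state$alpha_G)
  state$v <- st$v; state$p <- st$p; state$log1mv_sub <- st$log1mv
  state <- .update_rater_effects(state, y, d, fix_tau = fix_tau)
  state <- .update_rater_alloc(state, d, cfg$R_rater, fix_tau = fix_tau)
  state <- .update_rater_atoms(state, cfg, fix_tau = fix_tau)
  st <- .update_sticks(group_count(state$z, cfg$R_rater), state$alpha_H)
  state$u <- st$v; state$q <- st$p; state$log1mv_rat <- st$log1mv
  state$alpha_G <- .update_concentration(state$log1mv_sub,
                                         cfg$hyper$alpha_a,
                                         cfg$hyper$alpha_b)
  state$alpha_H <- .update_concentration(state$log1mv_rat,
                                         cfg$hyper$alpha_a,
                                         cfg$hyper$alpha_b)
  if (cfg$update_hyper) state <- .update_base_params(state, cfg)
  if (!all(is.finite(state$theta)) || !all(is.finite(state$b))) {
    stop("non-finite state encountered during Gibbs sweep")
  }
  state
}

# ---- prior simulation (Geweke-style checks) -------------------------------

# Draw base-measure parameters from their hyperpriors.
.draw_base_prior <- function(cfg) {
  h <- cfg$hyper
  center <- .scale_center(cfg)
  rinvgamma1 <- function(a, b) b / rgamma(1L, shape = a, rate = 1)
  list(m_mu = rnorm(1L, center, sqrt(1 / h$prec0_loc)),
       s2_mu = min(max(1 / rgamma(1L, h$a0, rate = h$b0), .VAR_FLOOR), 1e10),
       a_prec = h$base_shape,
       m_prec = max(rinvgamma1(h$a0, h$b0), 1e-12),
       m_beta = rnorm(1L, 0, sqrt(1 / h$prec0_loc)),
       s2_beta = min(max(1 / rgamma(1L, h$a0, rate = h$b0), .VAR_FLOOR), 1e10),
       a_om = h$base_shape,
       m_om = max(rinvgamma1(h$a0, h$b0), 1e-12),
       a_nu = h$base_shape,
       m_nu = h$m_nu0,
       c_eta = h$c_eta,
       d_eta = max(rgamma(1L, h$a0, rate = h$b0), 1e-12),
       center = center)
}

# Draw a full sampler state from the prior for a given design size.
.draw_state_prior <- function(d, cfg) {
  h <- cfg$hyper
  base <- .draw_base_prior(cfg)
  alpha_G <- rgamma(1L, h$alpha_a, rate = h$alpha_b)
  alpha_H <- rgamma(1L, h$alpha_a, rate = h$alpha_b)
  Rs <- cfg$R_subj; Rk <- cfg$R_rater
  v <- if (Rs > 1L) c(rbeta(Rs - 1L, 1, alpha_G), 1) else 1
  u <- if (Rk > 1L) c(rbeta(Rk - 1L, 1, alpha_H), 1) else 1
  v <- pmin(v, 1 - 1e-15); v[Rs] <- 1
  u <- pmin(u, 1 - 1e-15); u[Rk] <- 1
  p <- stick_weights(v); q <- stick_weights(u)
  sub_atoms <- draw_from_base("subject", base, Rs)
  rat_atoms <- draw_from_base("rater", base, Rk)
  cA <- sample.int(Rs, d$I, replace = TRUE, prob = p)
  zA <- sample.int(Rk, d$J, replace = TRUE, prob = q)
  theta <- rnorm(d$I, sub_atoms$mu[cA], sqrt(sub_atoms$sigma2[cA]))
  b <- rnorm(d$J, rat_atoms$beta[zA], sqrt(rat_atoms$omega2[zA]))
  s <- 1 + rat_atoms$nu[zA]
  tau <- pmax(rgamma(d$J, shape = s, rate = s / rat_atoms$eta[zA]), 1e-12)
  list(theta = theta, b = b, tau = tau, c = cA, z = zA,
       sub_atoms = sub_atoms, rat_atoms = rat_atoms,
       p = p, v = v, q = q, u = u,
       log1mv_sub = log1p(-v), log1mv_rat = log1p(-u),
       alpha_G = alpha_G, alpha_H = alpha_H, base = base,
       dm_failures = 0L)
}

# Simulate ratings from the current state (Geweke data step).
.simulate_data_from_state <- function(state, d) {
  mean_r <- state$theta[d$si] + state$b[d$ri]
  rnorm(d$N, mean_r, 1 / sqrt(state$tau[d$ri]))
}
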