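# Reduced model for one-way designs: rater identity is unidentifiable, so a
# DPM is placed over per-rating error terms e_n ~ N(delta_l, psi2_l) while
# the subject block is shared with the two-way model.

.init_state_oneway <- function(data, cfg) {
  d <- .dat_view(data)
  if (any(tabulate(d$si, d$I) == 0L)) stop("subject with zero ratings")
  y <- d$y
  center <- .scale_center(cfg)
  theta <- as.numeric(group_sum(y, d$si, d$I) / tabulate(d$si, d$I))
  r <- y - theta[d$si]
  base <- default_base_params(max(abs(center), 1))
  base$m_mu <- center
  base$a_prec <- base$a_om <- base$a_nu <- cfg$hyper$base_shape
  base$m_nu <- cfg$hyper$m_nu0
  base$c_eta <- cfg$hyper$c_eta
  # error base: delta ~ N(m_delta, s2_delta); 1/psi2 ~ Gamma(a_epr, m_epr)
  base$m_delta <- 0
  base$s2_delta <- max(var(r), 1)
  base$a_epr <- cfg$hyper$base_shape
  base$m_epr <- 1 / max(var(r), .VAR_FLOOR)

  Re <- cfg$R_rater    # error-mixture truncation reuses the rater slot
  K <- min(5L, Re)
  dn <- if (K == 1L) rep(1L, d$N) else {
    qs <- quantile(r, probs = seq(0, 1, length.out = K + 1L), names = FALSE)
    qs[1L] <- -Inf; qs[K + 1L] <- Inf
    as.integer(cut(r, breaks = unique(qs), include.lowest = TRUE))
  }
  delta <- numeric(Re); psi2 <- rep(max(var(r), 0.5), Re)
  for (l in seq_len(Re)) {
    xs <- r[dn == l]
    if (length(xs)) delta[l] <- mean(xs)
    if (length(xs) > 1L) psi2[l] <- max(var(xs), .VAR_FLOOR)
  }
  w <- tabulate(dn, Re); w <- ifelse(w > 0, 1, 0.01); w <- w / sum(w)
  cA <- {
    K <- min(5L, cfg$R_subj)
    if (K == 1L) rep(1L, d$I) else {
      qs <- quantile(theta, probs = seq(0, 1, length.out = K + 1L),
                     names = FALSE)
      qs[1L] <- -Inf; qs[K + 1L] <- Inf
      as.integer(cut(theta, breaks = unique(qs), include.lowest = TRUE))
    }
  }
  mu <- numeric(cfg$R_subj); s2 <- rep(max(var(theta), 1), cfg$R_subj)
  for (n in seq_len(cfg$R_subj)) {
    xs <- theta[cA == n]
    if (length(xs)) mu[n] <- mean(xs) else mu[n] <- mean(theta)
    if (length(xs) > 1L) s2[n] <- max(var(xs), .VAR_FLOOR)
  }
  wp <- tabulate(cA, cfg$R_subj); wp <- ifelse(wp > 0, 1, 0.01)
  list(theta = theta, c = cA,
       sub_atoms = list(mu = mu, sigma2 = s2),
       p = wp / sum(wp), v = rep(0.5, cfg$R_subj),
       dn = dn,
       err_atoms = list(delta = delta, psi2 = psi2),
       pe = w, ve = rep(0.5, Re),
       alpha_G = 1, alpha_E = 1,
       base = base, dm_failures = 0L)
}

.sweep_oneway <- function(state, y, d, cfg) {
  Re <- cfg$R_rater
  E <- state$err_atoms
  # subject true scores
  w_n <- 1 / E$psi2[state$dn]
  prec_lik <- group_sum(w_n, d$si, d$I)
  num_lik <- group_sum(w_n * (y - E$delta[state$dn]), d$si, d$I)
  mu_c <- state$sub_atoms$mu[state$c]
  s2_c <- state$sub_atoms$sigma2[state$c]
  post_prec <- 1 / s2_c + prec_lik
  post_mean <- (mu_c / s2_c + num_lik) / post_prec
  state$theta <- rnorm(d$I, post_mean, sqrt(1 / post_prec))
  # subject mixture
  state <- .update_subject_alloc(state, d, cfg$R_subj)
  state <- .update_subject_atoms(state, d, cfg)
  st <- .update_sticks(group_count(state$c, cfg$R_subj), state$alpha_G)
  state$v <- st$v; state$p <- st$p; state$log1mv_sub <- st$log1mv
  # error allocations
  r <- y - state$theta[d$si]
  if (Re > 1L) {
    logp <- matrix(log(pmax(state$pe, 1e-300)), d$N, Re, byrow = TRUE) +
      dnorm(matrix(r, d$N, Re),
            matrix(E$delta, d$N, Re, byrow = TRUE),
            matrix(sqrt(E$psi2), d$N, Re, byrow = TRUE), log = TRUE)
    state$dn <- sample_categorical_rows(softmax_rows(logp))
  }
  # error atoms (conjugate normal/gamma, empty refreshed from base)
  bp <- state$base
  nl <- group_count(state$dn, Re)
  S <- group_sum(r, state$dn, Re)
  post_prec <- 1 / bp$s2_delta + nl / E$psi2
  post_mean <- (bp$m_delta / bp$s2_delta + S / E$psi2) / post_prec
  delta <- rnorm(Re, post_mean, sqrt(1 / post_prec))
  SS <- group_sum((r - delta[state$dn])^2, state$dn, Re)
  prec <- rgamma(Re, shape = bp$a_epr + nl / 2,
                 rate = bp$a_epr / bp$m_epr + SS / 2)
  psi2 <- pmax(1 / prec, .VAR_FLOOR)
  empty <- nl == 0L
  if (any(empty)) {
    ne <- sum(empty)
    delta[empty] <- rnorm(ne, bp$m_delta, sqrt(bp$s2_delta))
    pe_ <- rgamma(ne, shape = bp$a_epr, rate = bp$a_epr / bp$m_epr)
    psi2[empty] <- pmax(1 / pe_, .VAR_FLOOR)
  }
  state$err_atoms <- list(delta = delta, psi2 = psi2)
  st <- .update_sticks(nl, state$alpha_E)
  state$ve <- st$v; state$pe <- st$p; state$log1mv_err <- st$log1mv
  state$alpha_G <- .update_concentration(state$log1mv_sub,
                                         cfg$hyper$alpha_a,
                                         cfg$hyper$alpha_b)
  state$alpha_E <- .update_concentration(state$log1mv_err,
                                         cfg$hyper$alpha_a,
                                         cfg$hyper$alpha_b)
  if (cfg$update_hyper) {
    state <- .update_base_params(state, cfg, rater_block = FALSE)
    # error base block
    h <- cfg$hyper
    bp <- state$base
    pp <- h$prec0_loc + Re / bp$s2_delta
    pm <- (sum(delta) / bp$s2_delta) / pp
    bp$m_delta <- rnorm(1L, pm, sqrt(1 / pp))
    prec_d <- rgamma(1L, shape = h$a0 + Re / 2,
                     rate = h$b0 + sum((delta - bp$m_delta)^2) / 2)
    bp$s2_delta <- min(max(1 / prec_d, .VAR_FLOOR), 1e10)
    lam <- 1 / psi2
    g <- rgamma(1L, shape = h$a0 + bp$a_epr * Re, rate = 1)
    bp$m_epr <- max((h$b0 + bp$a_epr * sum(lam)) / g, 1e-12)
    state$base <- bp
  }
  state
}

#' Exact ICC for one-way designs
#'
#' For two anonymous raters scoring the same random subject under the
#' one-way error mixture, the conditional correlation of the two ratings is
#' `var_theta / (var_theta + var_e)`, where `var_e` is the full mixture
#' variance of the per-rating error (between- plus within-component).
#' Exact because no expectation over heteroscedastic rater reliabilities is
#' involved; always in `[0, 1)`.
#'
#' @param var_theta subject true-score mixture variance (>= 0)
#' @param error_moments either a named vector with elements `mean` and `var`
#'   (as from [mixture_moments()] on the error atoms) or a single number,
#'   the error mixture variance
#' @return ICC value in `[0, 1)`
#' @export
icc_oneway <- function(var_theta, error_moments) {
  var_e <- if (length(error_moments) > 1L) {
    unname(error_moments["var"])
  } else {
    as.numeric(error_moments)
  }
  stopifnot(var_theta >= 0, var_e >= 0, var_theta + var_e > 0)
  var_theta / (var_theta + var_e)
}
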