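#' Fit a Bayesian nonparametric rating model
#'
#' Runs the truncated blocked Gibbs sampler for the two-way (crossed
#' subject-by-rater) heteroscedastic model, its one-way reduction, or the
#' ordinal (underlying-variable probit) extension, then applies the
#' semi-centering post-processing to every retained draw so that the rater
#' systematic-bias mixture has mean exactly zero (and, in the ordinal case,
#' the subject true-score mixture too, with the shifts absorbed into the
#' thresholds).
#'
#' @param data a [ratings()] table; ordinal tables select the ordinal
#'   likelihood automatically
#' @param variant `"BNP"` (both mixtures nonparametric), `"BSP"` (subjects
#'   nonparametric, raters single-cluster) or `"BP"` (fully parametric)
#' @param design `"two_way"` or `"one_way"`
#' @param iterations,burnin,thin,seed MCMC controls, see [rater_config()]
#' @param cfg optionally a ready-made [rater_config()]; overrides the other
#'   arguments
#' @param truth optional `scenario_truth` list (from [simulate_ratings()])
#'   kept with the fit for recovery evaluation
#' @param ... further arguments passed to [rater_config()]
#' @return an object of class `raterfit`; see [tidy.raterfit()],
#'   [glance.raterfit()], [posterior_icc()], [waic()], [density_grid()],
#'   [cluster_estimate()]
#' @export
fit_raters <- function(data, variant = c("BNP", "BSP", "BP"),
                       design = c("two_way", "one_way"),
                       iterations = 80000L, burnin = 20000L, thin = 60L,
                       seed = 1L, cfg = NULL, truth = NULL, ...) {
  stopifnot(inherits(data, "ratings_tbl"))
  ordinal <- !is.null(attr(data, "n_categories"))
  if (is.null(cfg)) {
    dots <- list(...)
    # a coarsened table carries its generating cutoffs: use them as the
    # thresholds, with the outer two fixed and the middle ones estimated
    if (ordinal && !"thresholds" %in% names(dots) &&
        !is.null(attr(data, "cutoffs"))) {
      dots$thresholds <- attr(data, "cutoffs")
    }
    cfg <- do.call(rater_config, c(list(
      variant = match.arg(variant), design = match.arg(design),
      likelihood = if (ordinal) "ordinal" else "continuous",
      iterations = iterations, burnin = burnin, thin = thin, seed = seed,
      scale_low = attr(data, "scale_low") %||% 1,
      scale_high = attr(data, "scale_high") %||% 100,
      n_categories = attr(data, "n_categories")), dots))
  }
  if (cfg$likelihood == "ordinal" && !ordinal) {
    stop("ordinal likelihood requires an ordinal ratings table")
  }
  set.seed(cfg$seed)
  d <- .dat_view(data)
  n_keep <- (cfg$iterations - cfg$burnin) %/% cfg$thin
  if (n_keep < 2L) stop("fewer than 2 retained draws; adjust MCMC controls")

  oneway <- cfg$design == "one_way"
  state <- if (oneway) .init_state_oneway(data, cfg) else init_state(data, cfg)

  Rs <- cfg$R_subj; Rk <- cfg$R_rater
  sc <- list(
    scalars = matrix(NA_real_, n_keep, 13L,
                     dimnames = list(NULL, c(
                       "mean_theta", "var_theta", "mean_b_raw", "var_b",
                       "mean_tau", "var_tau", "mean_residual_var", "icc_e",
                       "alpha_G", "alpha_H", "k_subj", "k_rater",
                       "dm_failures"))),
    theta = matrix(NA_real_, n_keep, d$I),
    c = matrix(NA_integer_, n_keep, d$I),
    sub_mu = matrix(NA_real_, n_keep, Rs),
    sub_sigma2 = matrix(NA_real_, n_keep, Rs),
    sub_p = matrix(NA_real_, n_keep, Rs),
    loglik = matrix(NA_real_, n_keep, d$N))
  if (oneway) {
    Re <- Rk
    sc$dn <- matrix(NA_integer_, n_keep, d$N)
    sc$err_delta <- matrix(NA_real_, n_keep, Re)
    sc$err_psi2 <- matrix(NA_real_, n_keep, Re)
    sc$err_p <- matrix(NA_real_, n_keep, Re)
  } else {
    sc$b <- matrix(NA_real_, n_keep, d$J)
    sc$tau <- matrix(NA_real_, n_keep, d$J)
    sc$z <- matrix(NA_integer_, n_keep, d$J)
    sc$rat_beta <- matrix(NA_real_, n_keep, Rk)
    sc$rat_omega2 <- matrix(NA_real_, n_keep, Rk)
    sc$rat_nu <- matrix(NA_real_, n_keep, Rk)
    sc$rat_eta <- matrix(NA_real_, n_keep, Rk)
    sc$rat_q <- matrix(NA_real_, n_keep, Rk)
  }
  if (cfg$likelihood == "ordinal") {
    sc$zeta <- matrix(NA_real_, n_keep, cfg$n_categories - 1L)
  }

  t <- 0L
  for (it in seq_len(cfg$iterations)) {
    state <- if (oneway) {
      .sweep_oneway(state, d$y, d, cfg)
    } else if (cfg$likelihood == "ordinal") {
      .sweep_ordinal(state, d, cfg)
    } else {
      .sweep_twoway(state, d$y, d, cfg)
    }
    if (it > cfg$burnin && (it - cfg$burnin) %% cfg$thin == 0L) {
      t <- t + 1L
      sc <- .store_draw(sc, t, state, d, cfg, oneway)
    }
  }
  if (state$dm_failures > 0L) {
    warning("derivatives-matching step hit its iteration cap ",
            state$dm_failures, " time(s) during the run; ",
            "last iterates were used (see the dm_failures diagnostic)")
  }
  structure(list(draws = sc, n_draws = n_keep, cfg = cfg, data = data,
                 truth = truth,
                 manifest = list(seed = cfg$seed,
                                 variant = cfg$variant,
                                 design = cfg$design,
                                 likelihood = cfg$likelihood,
                                 iterations = cfg$iterations,
                                 burnin = cfg$burnin, thin = cfg$thin,
                                 config_hash = rlang::hash(cfg),
                                 data_hash = rlang::hash(
                                   as.data.frame(data)[c("subject", "rater",
                                                         "rating")]),
                                 package_version =
                                   as.character(utils::packageVersion("raterdpm")),
                                 timestamp = format(Sys.time(), tz = "UTC"))),
            class = "raterfit")
}

# Store one retained draw with semi-centering (exact likelihood invariance).
.store_draw <- function(sc, t, state, d, cfg, oneway) {
  if (oneway) {
    me <- sum(state$pe * state$err_atoms$delta)
    delta <- state$err_atoms$delta - me
    theta <- state$theta + me
    mu <- state$sub_atoms$mu + me
    sm <- mixture_moments(state$p, mu, state$sub_atoms$sigma2)
    em <- mixture_moments(state$pe, delta, state$err_atoms$psi2)
    icc <- icc_oneway(unname(sm["var"]), em)
    ll <- dnorm(d$y, theta[d$si] + delta[state$dn],
                sqrt(state$err_atoms$psi2[state$dn]), log = TRUE)
    sc$scalars[t, ] <- c(sm["mean"], sm["var"], me, em["var"],
                         NA, NA, em["var"], icc,
                         state$alpha_G, state$alpha_E,
                         length(unique(state$c)),
                         length(unique(state$dn)), state$dm_failures)
    sc$theta[t, ] <- theta
    sc$c[t, ] <- state$c
    sc$sub_mu[t, ] <- mu
    sc$sub_sigma2[t, ] <- state$sub_atoms$sigma2
    sc$sub_p[t, ] <- state$p
    sc$dn[t, ] <- state$dn
    sc$err_delta[t, ] <- delta
    sc$err_psi2[t, ] <- state$err_atoms$psi2
    sc$err_p[t, ] <- state$pe
    return(sc)
  }
  A <- state$rat_atoms
  mb <- sum(state$q * A$beta)
  beta <- A$beta - mb
  b <- state$b - mb
  theta <- state$theta + mb
  mu <- state$sub_atoms$mu + mb
  zeta <- state$zeta
  if (cfg$likelihood == "ordinal") {
    # double-centering: subject mixture mean absorbed into the thresholds
    mtheta <- sum(state$p * mu)
    theta <- theta - mtheta
    mu <- mu - mtheta
    zeta <- zeta - mtheta
  }
  sm <- mixture_moments(state$p, mu, state$sub_atoms$sigma2)
  bm <- mixture_moments(state$q, beta, A$omega2)
  fix_tau <- cfg$likelihood == "ordinal" && cfg$n_categories == 2L
  if (fix_tau) {
    rel <- c(mean_tau = 1, var_tau = 0, mean_residual_var = 1)
  } else {
    rel <- reliability_moments(state$q, A, shifted = TRUE)
  }
  icc <- icc_E_bnp(unname(sm["var"]), unname(bm["var"]),
                   unname(rel["mean_residual_var"]))
  if (cfg$likelihood == "ordinal") {
    pr <- cell_probability(d$y, theta[d$si], b[d$ri], state$tau[d$ri], zeta)
    ll <- log(pmax(pr, 1e-300))
  } else {
    ll <- dnorm(d$y, theta[d$si] + b[d$ri],
                1 / sqrt(state$tau[d$ri]), log = TRUE)
  }
  sc$scalars[t, ] <- c(sm["mean"], sm["var"], mb, bm["var"],
                       rel["mean_tau"], rel["var_tau"],
                       rel["mean_residual_var"], icc,
                       state$alpha_G, state$alpha_H,
                       length(unique(state$c)), length(unique(state$z)),
                       state$dm_failures)
  sc$theta[t, ] <- theta
  sc$c[t, ] <- state$c
  sc$sub_mu[t, ] <- mu
  sc$sub_sigma2[t, ] <- state$sub_atoms$sigma2
  sc$sub_p[t, ] <- state$p
  sc$b[t, ] <- b
  sc$tau[t, ] <- state$tau
  sc$z[t, ] <- state$z
  sc$rat_beta[t, ] <- beta
  sc$rat_omega2[t, ] <- A$omega2
  sc$rat_nu[t, ] <- A$nu
  sc$rat_eta[t, ] <- A$eta
  sc$rat_q[t, ] <- state$q
  sc$loglik[t, ] <- ll
  if (cfg$likelihood == "ordinal") sc$zeta[t, ] <- zeta
  sc
}

#' Per-draw structural summaries of a fit
#'
#' @param fit a `raterfit`
#' @return tibble with one row per retained draw: mixture moments, mean
#'   residual variance, the population ICC lower bound `icc_e`, both
#'   concentration parameters and occupied-cluster counts
#' @export
posterior_draws <- function(fit) {
  stopifnot(inherits(fit, "raterfit"))
  out <- tibble::as_tibble(fit$draws$scalars)
  out$.draw <- seq_len(nrow(out))
  out
}

#' @export
print.raterfit <- function(x, ...) {
  cat(sprintf("<raterfit: %s %s %s model, %d subjects x %d raters, %d draws>\n",
              x$cfg$variant, x$cfg$design, x$cfg$likelihood,
              length(attr(x$data, "subjects")),
              length(attr(x$data, "raters")), x$n_draws))
  s <- posterior_draws(x)
  cat(sprintf("  var_theta %.3f  var_b %.3f  mean_residual_var %.3f  ICC_E %.3f\n",
              mean(s$var_theta), mean(s$var_b),
              mean(s$mean_residual_var), mean(s$icc_e)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of structural parameters
#'
#' @param x a `raterfit`
#' @param conf_level credible-interval level (equal-tailed quantiles)
#' @param ... unused
#' @return tibble with columns `term`, `estimate` (posterior mean),
#'   `conf.low`, `conf.high`
#' @export
tidy.raterfit <- function(x, conf_level = 0.95, ...) {
  s <- posterior_draws(x)
  terms <- c("mean_theta", "var_theta", "var_b", "mean_tau",
             "mean_residual_var", "icc_e", "alpha_G", "alpha_H")
  terms <- terms[terms %in% names(s)]
  a <- (1 - conf_level) / 2
  purrr::map_dfr(terms, function(tm) {
    v <- s[[tm]]
    if (all(is.na(v))) return(NULL)
    tibble::tibble(term = tm, estimate = mean(v),
                   conf.low = unname(quantile(v, a, na.rm = TRUE)),
                   conf.high = unname(quantile(v, 1 - a, na.rm = TRUE)))
  })
}

#' One-row fit summary
#'
#' @param x a `raterfit`
#' @param ... unused
#' @return tibble with model descriptors, posterior mean ICC_E, WAIC and
#'   effective number of parameters
#' @export
glance.raterfit <- function(x, ...) {
  w <- waic(x)
  s <- posterior_draws(x)
  tibble::tibble(variant = x$cfg$variant, design = x$cfg$design,
                 likelihood = x$cfg$likelihood,
                 n_subjects = length(attr(x$data, "subjects")),
                 n_raters = length(attr(x$data, "raters")),
                 n_records = nrow(x$data), n_draws = x$n_draws,
                 icc_e = mean(s$icc_e), waic = w$waic, p_waic = w$p_waic)
}

#' Posterior mean true scores per subject
#'
#' @param fit a `raterfit`
#' @param conf_level credible-interval level
#' @return tibble with `subject`, `estimate`, `conf.low`, `conf.high`
#' @export
true_scores <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "raterfit"))
  a <- (1 - conf_level) / 2
  th <- fit$draws$theta
  tibble::tibble(subject = attr(fit$data, "subjects"),
                 estimate = colMeans(th),
                 conf.low = apply(th, 2L, quantile, a),
                 conf.high = apply(th, 2L, quantile, 1 - a))
}
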