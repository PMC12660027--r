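#' Parametric intraclass correlation
#'
#' Proportion of rating variance due to the subjects' true score:
#' `var_theta / (var_theta + var_b + residual_var)`. Cannot capture
#' negative correlation; always in `[0, 1)`.
#'
#' @param var_theta true-score variance (>= 0)
#' @param var_b rater systematic-bias variance (>= 0)
#' @param residual_var residual variance (> 0 unless `var_theta > 0`)
#' @return ICC in `[0, 1)`
#' @export
icc_parametric <- function(var_theta, var_b, residual_var) {
  stopifnot(all(var_theta >= 0), all(var_b >= 0), all(residual_var >= 0),
            all(var_theta + var_b + residual_var > 0))
  var_theta / (var_theta + var_b + residual_var)
}

#' Pairwise ICC for two specific raters
#'
#' Conditional correlation of the ratings that raters with precisions
#' `tau_j` and `tau_jp` give to a random subject:
#' `var_theta / sqrt((var_theta + var_b + 1/tau_j) *
#'                   (var_theta + var_b + 1/tau_jp))`.
#' Symmetric in the two raters; reduces to [icc_parametric()] when both
#' precisions equal the inverse residual variance.
#'
#' @inheritParams icc_parametric
#' @param tau_j,tau_jp the two raters' precisions (> 0)
#' @return ICC in `[0, 1)`
#' @export
icc_pairwise <- function(var_theta, var_b, tau_j, tau_jp) {
  stopifnot(all(tau_j > 0), all(tau_jp > 0))
  var_theta / sqrt((var_theta + var_b + 1 / tau_j) *
                     (var_theta + var_b + 1 / tau_jp))
}

#' Parametric ICC at average reliability (ICC_E)
#'
#' Replaces the rater-specific residual variance with its expectation under
#' the shifted-shape gamma reliability law `tau ~ Gamma(1 + nu, mean eta)`:
#' `E[1/tau] = (1 + nu) / (nu * eta)`, plugged into the parametric ICC.
#'
#' @inheritParams icc_parametric
#' @param nu pre-shift gamma shape of the reliability law (> 0)
#' @param eta reliability mean (> 0)
#' @return ICC in `[0, 1)`
#' @export
icc_E_parametric <- function(var_theta, var_b, nu, eta) {
  stopifnot(all(nu > 0), all(eta > 0))
  icc_parametric(var_theta, var_b, (1 + nu) / (nu * eta))
}

#' BNP conditional ICC for a rater pair
#'
#' Conditional correlation of two raters' ratings of a random subject given
#' the raters' reliabilities, under the full mixture model: the subject and
#' bias variances are the mixture variances, so
#' `rho = var_theta / sqrt((var_theta + var_b + 1/tau_j) *
#'                         (var_theta + var_b + 1/tau_jp))`.
#' Reduces to the parametric pairwise ICC when both mixtures are degenerate
#' on single components.
#'
#' @param subject_moments named vector with `var_theta` (e.g. from
#'   [subject_moments()]) or a single number, the mixture variance
#' @param bias_moments named vector with `var_b` (from
#'   [rater_bias_moments()]) or a single number
#' @param tau_j,tau_jp the two raters' precisions
#' @return ICC in `[0, 1)`
#' @export
icc_conditional_bnp <- function(subject_moments, bias_moments,
                                tau_j, tau_jp) {
  vt <- if (length(subject_moments) > 1L)
    unname(subject_moments["var_theta"]) else as.numeric(subject_moments)
  vb <- if (length(bias_moments) > 1L)
    unname(bias_moments["var_b"]) else as.numeric(bias_moments)
  icc_pairwise(vt, vb, tau_j, tau_jp)
}

#' BNP population ICC lower bound (ICC_E)
#'
#' `var_theta / (var_theta + var_b + mean_residual_var)` with all three
#' quantities mixture moments. By Jensen's inequality (the map
#' `x -> 1/sqrt(D + x)` is convex) this is a certified lower bound of the
#' expected pairwise ICC over random rater pairs; it equals the parametric
#' ICC when every mixture is degenerate on one component.
#'
#' @param var_theta subject mixture variance
#' @param var_b bias mixture variance
#' @param mean_residual_var mixture mean of the residual variance
#'   (`mean_residual_var` from [reliability_moments()])
#' @return ICC_E in `[0, 1)`
#' @export
icc_E_bnp <- function(var_theta, var_b, mean_residual_var) {
  icc_parametric(var_theta, var_b, mean_residual_var)
}

#' Posterior distribution of an ICC index
#'
#' Computes the chosen ICC flavor at every retained draw and summarizes it
#' with the posterior mean and an equal-tailed quantile credible interval.
#'
#' @param fit a `raterfit`
#' @param flavor `"bnp"` (default: the ICC_E lower bound from the mixture
#'   moments, which on a single-component fit equals the parametric index),
#'   `"parametric"` (same functional evaluated on the fit's moments;
#'   identical to `"bnp"` under `R = 1` truncation), `"one_way"` (exact
#'   one-way index) or `"pairwise_mc"` (Monte-Carlo expected pairwise ICC
#'   over `n_pairs` random rater pairs per draw)
#' @param conf_level credible level
#' @param n_pairs pair budget per draw for `"pairwise_mc"`
#' @return an `icc_report` list: per-draw values, posterior mean, interval
#'   bounds, flavor
#' @export
posterior_icc <- function(fit, flavor = c("bnp", "parametric", "one_way",
                                          "pairwise_mc"),
                          conf_level = 0.95, n_pairs = 200L) {
  stopifnot(inherits(fit, "raterfit"))
  flavor <- match.arg(flavor)
  s <- posterior_draws(fit)
  vals <- switch(
    flavor,
    bnp = ,
    parametric = s$icc_e,
    one_way = {
      if (fit$cfg$design != "one_way") {
        stop("one_way flavor requires a one-way fit")
      }
      s$icc_e
    },
    pairwise_mc = {
      if (fit$cfg$design == "one_way") stop("pairwise ICC needs rater draws")
      vapply(seq_len(fit$n_draws), function(t) {
        q <- fit$draws$rat_q[t, ]
        nu <- fit$draws$rat_nu[t, ]
        eta <- fit$draws$rat_eta[t, ]
        k1 <- sample.int(length(q), n_pairs, replace = TRUE, prob = q)
        k2 <- sample.int(length(q), n_pairs, replace = TRUE, prob = q)
        s1 <- 1 + nu[k1]; s2 <- 1 + nu[k2]
        t1 <- rgamma(n_pairs, s1, rate = s1 / eta[k1])
        t2 <- rgamma(n_pairs, s2, rate = s2 / eta[k2])
        mean(icc_pairwise(s$var_theta[t], s$var_b[t], t1, t2))
      }, numeric(1L))
    })
  a <- (1 - conf_level) / 2
  structure(list(values = vals, mean = mean(vals),
                 conf.low = unname(quantile(vals, a)),
                 conf.high = unname(quantile(vals, 1 - a)),
                 conf_level = conf_level, flavor = flavor),
            class = "icc_report")
}

#' @export
print.icc_report <- function(x, ...) {
  cat(sprintf("ICC (%s): posterior mean %.3f, %g%% CI [%.3f, %.3f]\n",
              x$flavor, x$mean, 100 * x$conf_level, x$conf.low, x$conf.high))
  invisible(x)
}
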