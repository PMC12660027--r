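#' Scenario specification for synthetic rating data
#'
#' Describes a generative process for an unbalanced two-way rating design
#' with clustered subject true scores and clustered rater bias/reliability,
#' or (with an `error` block) a one-way design with a per-rating error
#' mixture.
#'
#' @param name scenario label
#' @param I,J,k number of subjects, raters, and ratings per subject
#' @param subject list with equal-length vectors `w` (weights summing to
#'   1), `location`, `scale` (component SD) and optional `slant`
#'   (skew-normal slant, 0 = normal)
#' @param rater list with vectors `w`, `beta` (bias mean), `omega2` (bias
#'   variance), `nu` (reliability pre-shift shape) and `eta` (reliability
#'   mean); reliabilities are drawn `Gamma(1 + nu, mean eta)`
#' @param error optional list with vectors `w`, `delta` (error mean) and
#'   `psi2` (error variance) for one-way generation; supersedes `rater`
#' @param scale_low,scale_high nominal rating-scale bounds (generated
#'   ratings may exceed them: the model is unbounded, bounds are flagged
#'   with a warning attribute, not clipped)
#' @return a `scenario_spec` list
#' @export
scenario_spec <- function(name, I, J, k, subject, rater = NULL,
                          error = NULL,
                          scale_low = 1, scale_high = 100) {
  stopifnot(abs(sum(subject$w) - 1) < 1e-8)
  if (is.null(subject$slant)) subject$slant <- rep(0, length(subject$w))
  stopifnot(length(subject$w) == length(subject$location),
            length(subject$w) == length(subject$scale),
            length(subject$w) == length(subject$slant))
  if (!is.null(rater)) {
    stopifnot(abs(sum(rater$w) - 1) < 1e-8,
              all(rater$nu > 0), all(rater$eta > 0), all(rater$omega2 > 0))
  }
  if (!is.null(error)) {
    stopifnot(abs(sum(error$w) - 1) < 1e-8, all(error$psi2 > 0))
  }
  structure(list(name = name, I = as.integer(I), J = as.integer(J),
                 k = as.integer(k), subject = subject, rater = rater,
                 error = error,
                 scale_low = scale_low, scale_high = scale_high),
            class = "scenario_spec")
}

#' Preset simulation scenarios
#'
#' Three generative presets with increasing population heterogeneity on a
#' 1-100 scale with 300 subjects and 50 raters:
#' * `unimodal` - one subject component, one rater component: the
#'   correctly-specified parametric case.
#' * `bimodal` - two subject proficiency clusters about two mixture SDs
#'   apart; raters either slightly lenient and reliable or more severe and
#'   less reliable.
#' * `multimodal` - three poorly separated skew-normal subject clusters
#'   giving a negatively skewed true-score density; three rater clusters.
#'
#' @param k ratings per subject (2 by default; 5 is the other study arm)
#' @param I,J design sizes
#' @return named list of [scenario_spec()] objects
#' @export
default_scenarios <- function(k = 2L, I = 300L, J = 50L) {
  list(
    unimodal = scenario_spec(
      "unimodal", I, J, k,
      subject = list(w = 1, location = 55, scale = 6),
      rater = list(w = 1, beta = 0, omega2 = 2.25, nu = 5, eta = 0.1)),
    bimodal = scenario_spec(
      "bimodal", I, J, k,
      subject = list(w = c(0.5, 0.5), location = c(44, 66),
                     scale = c(6, 6)),
      rater = list(w = c(0.6, 0.4), beta = c(1.5, -3),
                   omega2 = c(1, 2.25), nu = c(6, 3), eta = c(0.2, 0.05))),
    multimodal = scenario_spec(
      "multimodal", I, J, k,
      subject = list(w = c(0.45, 0.35, 0.2),
                     location = c(72, 58, 38), scale = c(8, 7, 9),
                     slant = c(-5, -3, -2)),
      rater = list(w = c(0.4, 0.35, 0.25), beta = c(-4, 0, 3),
                   omega2 = c(2.25, 1, 1.5), nu = c(3, 5, 6),
                   eta = c(0.08, 0.15, 0.25))))
}

#' Population truth implied by a scenario
#'
#' Closed-form mixture moments (skew-normal component moments where
#' slanted) and the implied population ICC_E, computed with the same moment
#' operations used on posterior draws.
#'
#' @param spec a [scenario_spec()]
#' @return list with `mean_theta`, `var_theta`, `var_b`,
#'   `mean_residual_var`, `icc_e` (or `var_e` and one-way `icc_e` for
#'   error-block scenarios)
#' @export
scenario_moments <- function(spec) {
  sj <- spec$subject
  cm <- skewnorm_moments(sj$location, sj$scale, sj$slant)
  sm <- mixture_moments(sj$w, cm$mean, cm$var)
  out <- list(mean_theta = unname(sm["mean"]), var_theta = unname(sm["var"]))
  if (!is.null(spec$error)) {
    em <- mixture_moments(spec$error$w, spec$error$delta, spec$error$psi2)
    out$var_e <- unname(em["var"]) +
      unname(em["mean"])^2 * 0  # centered below at generation
    out$mean_e <- unname(em["mean"])
    out$icc_e <- icc_oneway(out$var_theta, unname(em["var"]))
    return(out)
  }
  rt <- spec$rater
  bm <- mixture_moments(rt$w, rt$beta, rt$omega2)
  rel <- reliability_moments(rt$w, list(nu = rt$nu, eta = rt$eta))
  out$mean_b <- unname(bm["mean"])
  out$var_b <- unname(bm["var"])
  out$mean_tau <- unname(rel["mean_tau"])
  out$mean_residual_var <- unname(rel["mean_residual_var"])
  out$icc_e <- icc_E_bnp(out$var_theta, out$var_b, out$mean_residual_var)
  out
}

#' Assign raters to subjects in an unbalanced crossed design
#'
#' Each subject receives `k` distinct raters taken consecutively from a
#' cyclic random rater permutation, so workloads stay approximately
#' balanced while the design remains unbalanced in general.
#'
#' @param I,J,k subjects, raters, ratings per subject (`k <= J`)
#' @return integer matrix `I x k` of rater indices
#' @export
generate_design <- function(I, J, k) {
  stopifnot(k <= J, I >= 1, J >= 1)
  perm <- sample.int(J)
  t(vapply(seq_len(I), function(i) {
    start <- ((i - 1L) * k) %% J
    perm[((start + seq_len(k) - 1L) %% J) + 1L]
  }, integer(k)))
}

#' Simulate a rating data set from a scenario
#'
#' Draws component memberships, individual true scores and rater (or
#' error) parameters from the scenario's mixtures, assigns raters by
#' [generate_design()], and generates ratings by the additive decomposition
#' `y = theta + b + residual` with rater-specific residual precision (or
#' `y = theta + e` in the one-way case). The exact generating values and
#' population moments are attached as a `scenario_truth` attribute for
#' recovery evaluation.
#'
#' @param spec a [scenario_spec()] or the name of a [default_scenarios()]
#'   preset
#' @param seed integer seed
#' @param ... arguments forwarded to [default_scenarios()] when `spec` is a
#'   preset name (e.g. `k`, `I`, `J`)
#' @return a [ratings()] table with attribute `truth`; ratings falling
#'   outside the nominal scale are kept unclipped and counted in the
#'   truth's `n_out_of_scale`
#' @export
simulate_ratings <- function(spec, seed = 1L, ...) {
  if (is.character(spec)) {
    presets <- default_scenarios(...)
    if (!spec %in% names(presets)) {
      stop("unknown scenario '", spec, "'; available: ",
           paste(names(presets), collapse = ", "))
    }
    spec <- presets[[spec]]
  }
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(seed)
  I <- spec$I; J <- spec$J; k <- spec$k
  sj <- spec$subject
  c_true <- sample.int(length(sj$w), I, replace = TRUE, prob = sj$w)
  theta <- rskewnorm(I, sj$location[c_true], sj$scale[c_true],
                     sj$slant[c_true])
  mom <- scenario_moments(spec)
  if (!is.null(spec$error)) {
    # one-way: every rating has its own anonymous rater
    er <- spec$error
    delta <- er$delta - sum(er$w * er$delta)   # centered error means
    si <- rep(seq_len(I), each = k)
    N <- length(si)
    l_true <- sample.int(length(er$w), N, replace = TRUE, prob = er$w)
    e <- rnorm(N, delta[l_true], sqrt(er$psi2[l_true]))
    y <- theta[si] + e
    df <- data.frame(subject = sprintf("s%03d", si),
                     rater = sprintf("r%05d", seq_len(N)), rating = y)
    truth <- list(spec = spec, theta = theta, c_true = c_true,
                  l_true = l_true,
                  mean_theta = mom$mean_theta, var_theta = mom$var_theta,
                  var_e = unname(mixture_moments(er$w, delta, er$psi2)["var"]),
                  icc_e = mom$icc_e)
  } else {
    rt <- spec$rater
    z_true <- sample.int(length(rt$w), J, replace = TRUE, prob = rt$w)
    b <- rnorm(J, rt$beta[z_true], sqrt(rt$omega2[z_true]))
    s <- 1 + rt$nu[z_true]
    tau <- rgamma(J, shape = s, rate = s / rt$eta[z_true])
    design <- generate_design(I, J, k)
    si <- rep(seq_len(I), each = k)
    ri <- as.integer(t(design))
    N <- length(si)
    y <- theta[si] + b[ri] + rnorm(N, 0, 1 / sqrt(tau[ri]))
    df <- data.frame(subject = sprintf("s%03d", si),
                     rater = sprintf("r%03d", ri), rating = y)
    truth <- list(spec = spec, theta = theta, b = b, tau = tau,
                  c_true = c_true, z_true = z_true,
                  mean_theta = mom$mean_theta, var_theta = mom$var_theta,
                  var_b = mom$var_b,
                  mean_residual_var = mom$mean_residual_var,
                  icc_e = mom$icc_e)
  }
  n_out <- sum(df$rating < spec$scale_low | df$rating > spec$scale_high)
  truth$n_out_of_scale <- n_out
  if (n_out > 0L) {
    warning(n_out, " generated rating(s) fall outside the nominal scale [",
            spec$scale_low, ", ", spec$scale_high,
            "]; kept unclipped (the model is unbounded)")
  }
  out <- ratings(df, scale_low = spec$scale_low,
                 scale_high = spec$scale_high, .validate_scale = FALSE)
  attr(out, "truth") <- truth
  out
}

#' Generating truth attached to a simulated table
#'
#' @param data a table from [simulate_ratings()]
#' @return the `scenario_truth` list
#' @export
scenario_truth <- function(data) {
  tr <- attr(data, "truth")
  if (is.null(tr)) stop("no scenario truth attached to this table")
  tr
}
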