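# Shared fixtures, built in code.

toy_ratings <- function() {
  ratings(data.frame(
    subject = c("s1", "s1", "s2", "s2"),
    rater = c("r1", "r2", "r1", "r2"),
    rating = c(30, 35, 12, 18)), scale_low = 1, scale_high = 50)
}

# A random finite mixture for moment-oracle checks.
random_subject_mixture <- function(R = 5L) {
  v <- c(rbeta(R - 1L, 1, 1), 1)
  list(w = stick_weights(v),
       atoms = list(mu = rnorm(R, 50, 10),
                    sigma2 = rgamma(R, 3, rate = 0.5)))
}

random_rater_mixture <- function(R = 4L) {
  v <- c(rbeta(R - 1L, 1, 1), 1)
  list(w = stick_weights(v),
       atoms = list(beta = rnorm(R, 0, 3),
                    omega2 = rgamma(R, 3, rate = 1),
                    nu = rgamma(R, 4, rate = 1) + 0.2,
                    eta = rgamma(R, 4, rate = 4) + 0.05))
}

# Draw true scores / biases / reliabilities from a mixture (sampling oracle).
draw_theta <- function(n, w, atoms) {
  k <- sample.int(length(w), n, replace = TRUE, prob = w)
  rnorm(n, atoms$mu[k], sqrt(atoms$sigma2[k]))
}

draw_bias <- function(n, w, atoms) {
  k <- sample.int(length(w), n, replace = TRUE, prob = w)
  rnorm(n, atoms$beta[k], sqrt(atoms$omega2[k]))
}

draw_tau <- function(n, w, atoms) {
  k <- sample.int(length(w), n, replace = TRUE, prob = w)
  s <- 1 + atoms$nu[k]
  rgamma(n, shape = s, rate = s / atoms$eta[k])
}

# Small well-separated bimodal scenario used by clustering tests.
separated_bimodal_spec <- function(I = 80L, J = 16L, k = 4L) {
  scenario_spec(
    "separated-bimodal", I, J, k,
    subject = list(w = c(0.5, 0.5), location = c(35, 75), scale = c(4, 4)),
    rater = list(w = 1, beta = 0, omega2 = 1, nu = 6, eta = 0.5))
}

desk_cfg <- function(...) {
  rater_config(iterations = 600L, burnin = 200L, thin = 2L, ...)
}
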