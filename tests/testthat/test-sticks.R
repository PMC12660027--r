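test_that("stick weights follow the truncated stick-breaking closed form", {
  expect_equal(stick_weights(c(1, 0.3, 0.9)), c(1, 0, 0))
  expect_equal(stick_weights(c(0.5, 0.5, 1)), c(0.5, 0.25, 0.25))
  expect_error(stick_weights(c(0.5, 1.2)), "\\[0, 1\\]")
  # exact unit sum after the renormalization guard, any fractions
  set.seed(1)
  for (i in 1:25) {
    v <- runif(sample(2:30, 1))
    expect_identical(sum(stick_weights(v)), 1)
    expect_true(all(stick_weights(v) >= 0))
  }
})

test_that("first stick weight matches the Beta(1, alpha) expectation", {
  set.seed(42)
  alpha <- 0.5
  p1 <- rbeta(1e5, 1, alpha)   # p_1 = v_1
  expect_equal(mean(p1), 1 / (1 + alpha),
               tolerance = 3 * sd(p1) / sqrt(1e5) / (1 / (1 + alpha)))
})

test_that("mixture moments reduce correctly on degenerate cases", {
  expect_equal(subject_moments(1, list(mu = 50, sigma2 = 4)),
               c(mean_theta = 50, var_theta = 4))
  expect_equal(subject_moments(c(0.5, 0.5),
                               list(mu = c(-1, 1), sigma2 = c(0, 0))),
               c(mean_theta = 0, var_theta = 1))
  expect_equal(rater_bias_moments(1, list(beta = 0, omega2 = 1)),
               c(mean_b = 0, var_b = 1))
  expect_equal(rater_bias_moments(c(0.5, 0.5),
                                  list(beta = c(-2, 2),
                                       omega2 = c(0.1, 0.1))),
               c(mean_b = 0, var_b = 4.1))
})

test_that("reliability moments use the shifted-shape inverse mean", {
  # single component, shifted shape 2 (nu = 1), mean 1: E[1/tau] = 2/(1*1)
  m <- reliability_moments(1, list(nu = 1, eta = 1))
  expect_equal(unname(m["mean_residual_var"]), 2)
  expect_equal(unname(m["mean_tau"]), 1)
  # shape -> infinity at mean m: residual variance -> 1/m
  m <- reliability_moments(1, list(nu = 1e8, eta = 4))
  expect_equal(unname(m["mean_residual_var"]), 0.25, tolerance = 1e-6)
  expect_lt(unname(m["var_tau"]), 1e-6)
  # unshifted path requires shape > 1
  expect_error(reliability_moments(1, list(nu = 0.5, eta = 1),
                                   shifted = FALSE), "reparametrization")
})

test_that("moment operations agree with sampling oracles on random mixtures", {
  set.seed(7)
  n <- 2e5
  for (rep in 1:8) {
    sm <- random_subject_mixture(sample(2:6, 1))
    th <- draw_theta(n, sm$w, sm$atoms)
    mom <- subject_moments(sm$w, sm$atoms)
    se_m <- sd(th) / sqrt(n)
    expect_equal(unname(mom["mean_theta"]), mean(th), tolerance = Inf)
    expect_lt(abs(mom["mean_theta"] - mean(th)), 3 * se_m)
    se_v <- sd((th - mean(th))^2) / sqrt(n)
    expect_lt(abs(mom["var_theta"] - var(th)), 3 * se_v)

    rm_ <- random_rater_mixture(sample(2:5, 1))
    ta <- draw_tau(n, rm_$w, rm_$atoms)
    mm <- reliability_moments(rm_$w, rm_$atoms)
    expect_lt(abs(mm["mean_tau"] - mean(ta)), 3 * sd(ta) / sqrt(n))
    inv <- 1 / ta
    expect_lt(abs(mm["mean_residual_var"] - mean(inv)),
              3 * sd(inv) / sqrt(n))
  }
})

test_that("R = 1 truncation reduces every moment to its parametric value", {
  atoms <- list(mu = 12, sigma2 = 9)
  expect_equal(subject_moments(1, atoms),
               c(mean_theta = 12, var_theta = 9))
  r <- list(beta = -1, omega2 = 2, nu = 3, eta = 0.5)
  expect_equal(unname(rater_bias_moments(1, r)), c(-1, 2))
  expect_equal(unname(reliability_moments(1, r)["mean_residual_var"]),
               4 / (0.5 * 3))
})

test_that("base-measure draws are reproducible and centered as specified", {
  params <- default_base_params(50)
  expect_length(draw_from_base("subject", params, 0)$mu, 0)
  set.seed(5); a1 <- draw_from_base("rater", params, 10)
  set.seed(5); a2 <- draw_from_base("rater", params, 10)
  expect_identical(a1, a2)
  set.seed(6)
  big <- draw_from_base("subject", params, 1e5)
  se <- sqrt(params$s2_mu / 1e5)
  expect_lt(abs(mean(big$mu) - params$m_mu), 3 * se)
  expect_true(all(big$sigma2 > 0))
})
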