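test_that("parametric ICC closed forms", {
  expect_equal(icc_parametric(1, 0, 1), 0.5)
  expect_equal(icc_parametric(0, 1, 1), 0)
  expect_equal(icc_parametric(2, 1, 1), 0.5)
  expect_error(icc_parametric(-1, 0, 1))
})

test_that("pairwise ICC is symmetric and reduces to the parametric form", {
  expect_equal(icc_pairwise(1, 0, 1, 1), 0.5)
  expect_equal(icc_pairwise(2, 0.5, 0.7, 1.9),
               icc_pairwise(2, 0.5, 1.9, 0.7))
  # equal precisions at the inverse residual variance recover the
  # homoscedastic parametric index
  expect_equal(icc_pairwise(3, 1, 1 / 2, 1 / 2), icc_parametric(3, 1, 2))
})

test_that("pairwise ICC matches the empirical correlation of rating pairs", {
  set.seed(21)
  n <- 4e5
  for (rep in 1:5) {
    vt <- rgamma(1, 3); vb <- rgamma(1, 2); t1 <- rgamma(1, 2)
    t2 <- rgamma(1, 2)
    theta <- rnorm(n, 0, sqrt(vt))
    y1 <- theta + rnorm(n, 0, sqrt(vb)) + rnorm(n, 0, 1 / sqrt(t1))
    y2 <- theta + rnorm(n, 0, sqrt(vb)) + rnorm(n, 0, 1 / sqrt(t2))
    r_emp <- cor(y1, y2)
    se <- (1 - r_emp^2) / sqrt(n)
    # 3.5 SE: familywise bound over the five replicated comparisons
    expect_lt(abs(icc_pairwise(vt, vb, t1, t2) - r_emp), 3.5 * se)
  }
})

test_that("ICC_E parametric uses the inverse-gamma mean", {
  # shifted shape 2 + mean 1 reliability: E[1/tau] = 2, so ICC = 1/(1+1+2)
  expect_equal(icc_E_parametric(1, 1, nu = 1, eta = 1), 0.25)
  # degenerate reliability at tau = 1
  expect_equal(icc_E_parametric(1, 0, nu = 1e9, eta = 1), 0.5,
               tolerance = 1e-8)
})

test_that("BNP conditional ICC reduces and matches the pair oracle", {
  sm <- c(mean_theta = 0, var_theta = 2)
  bm <- c(mean_b = 0, var_b = 0.5)
  expect_equal(icc_conditional_bnp(sm, bm, 1, 1), icc_pairwise(2, 0.5, 1, 1))
  expect_equal(icc_conditional_bnp(c(mean_theta = 0, var_theta = 0), bm,
                                   1, 2), 0)
  set.seed(9)
  n <- 4e5
  smx <- random_subject_mixture(3)
  rmx <- random_rater_mixture(2)
  vt <- unname(subject_moments(smx$w, smx$atoms)["var_theta"])
  vb <- unname(rater_bias_moments(rmx$w, rmx$atoms)["var_b"])
  t1 <- 0.8; t2 <- 2.5
  theta <- draw_theta(n, smx$w, smx$atoms)
  y1 <- theta + draw_bias(n, rmx$w, rmx$atoms) + rnorm(n, 0, 1 / sqrt(t1))
  y2 <- theta + draw_bias(n, rmx$w, rmx$atoms) + rnorm(n, 0, 1 / sqrt(t2))
  r_emp <- cor(y1, y2)
  expect_lt(abs(icc_conditional_bnp(vt, vb, t1, t2) - r_emp),
            3 * (1 - r_emp^2) / sqrt(n))
})

test_that("ICC_E lower-bounds the expected pairwise ICC (Jensen)", {
  set.seed(31)
  for (rep in 1:10) {
    smx <- random_subject_mixture(sample(2:5, 1))
    rmx <- random_rater_mixture(sample(2:4, 1))
    vt <- unname(subject_moments(smx$w, smx$atoms)["var_theta"])
    vb <- unname(rater_bias_moments(rmx$w, rmx$atoms)["var_b"])
    mrv <- unname(reliability_moments(rmx$w, rmx$atoms)["mean_residual_var"])
    lower <- icc_E_bnp(vt, vb, mrv)
    npair <- 1e4
    t1 <- draw_tau(npair, rmx$w, rmx$atoms)
    t2 <- draw_tau(npair, rmx$w, rmx$atoms)
    pij <- icc_pairwise(vt, vb, t1, t2)
    se <- sd(pij) / sqrt(npair)
    expect_lt(lower, mean(pij) + 3 * se)
    expect_true(lower >= 0 && lower < 1)
  }
})

test_that("degeneracy chain: BNP -> parametric under single components", {
  vt <- 2.2; vb <- 0.8; nu <- 4; eta <- 0.9
  mrv <- unname(reliability_moments(1, list(nu = nu, eta = eta))[
    "mean_residual_var"])
  expect_equal(icc_E_bnp(vt, vb, mrv), icc_E_parametric(vt, vb, nu, eta))
  expect_equal(icc_E_bnp(vt, vb, mrv),
               icc_parametric(vt, vb, (1 + nu) / (nu * eta)))
  # var_b -> infinity drives the index to zero
  expect_lt(icc_E_bnp(vt, 1e12, mrv), 1e-10)
})

test_that("one-way ICC matches the pair-sampling oracle and limits", {
  expect_equal(icc_oneway(1, c(mean = 0, var = 1)), 0.5)
  expect_equal(icc_oneway(0, c(mean = 0, var = 2)), 0)
  set.seed(12)
  n <- 4e5
  w <- c(0.3, 0.7); delta0 <- c(-2, 6/7); delta <- delta0 - sum(w * delta0)
  psi2 <- c(0.5, 1.5)
  vt <- 3
  em <- mixture_moments(w, delta, psi2)
  theta <- rnorm(n, 0, sqrt(vt))
  draw_e <- function() {
    k <- sample.int(2, n, replace = TRUE, prob = w)
    rnorm(n, delta[k], sqrt(psi2[k]))
  }
  y1 <- theta + draw_e(); y2 <- theta + draw_e()
  r_emp <- cor(y1, y2)
  expect_lt(abs(icc_oneway(vt, em) - r_emp), 3 * (1 - r_emp^2) / sqrt(n))
  # monotone in var_theta with error moments held fixed
  vals <- vapply(c(0.5, 1, 2, 4), icc_oneway, numeric(1),
                 error_moments = em)
  expect_true(all(diff(vals) > 0))
})
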