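random_raw_draw <- function(I = 6L, J = 4L, Rs = 3L, Rk = 2L) {
  list(theta = rnorm(I, 50, 5), b = rnorm(J),
       sub_atoms = list(mu = rnorm(Rs, 50, 5), sigma2 = rgamma(Rs, 2)),
       rat_atoms = list(beta = rnorm(Rk), omega2 = rgamma(Rk, 2),
                        nu = rgamma(Rk, 2) + 0.1, eta = rgamma(Rk, 2) + 0.1),
       p = stick_weights(c(runif(Rs - 1), 1)),
       q = stick_weights(c(runif(Rk - 1), 1)))
}

test_that("semi-centering zeroes the bias mean and preserves predictors", {
  set.seed(77)
  for (i in 1:10) {
    dr <- random_raw_draw()
    ce <- semi_center(dr)
    expect_lt(abs(sum(ce$q * ce$rat_atoms$beta)), 1e-12)
    si <- sample(6, 12, TRUE); ri <- sample(4, 12, TRUE)
    expect_equal(ce$theta[si] + ce$b[ri], dr$theta[si] + dr$b[ri],
                 tolerance = 1e-12)
    # gauge invariance: shifting b by delta and theta by -delta first
    # yields the same centered draw
    delta <- rnorm(1)
    dr2 <- dr
    dr2$b <- dr$b + delta; dr2$rat_atoms$beta <- dr$rat_atoms$beta + delta
    dr2$theta <- dr$theta - delta; dr2$sub_atoms$mu <- dr$sub_atoms$mu - delta
    ce2 <- semi_center(dr2)
    expect_equal(ce2$b, ce$b, tolerance = 1e-10)
    expect_equal(ce2$theta, ce$theta, tolerance = 1e-10)
    # already centered draws are left untouched
    expect_equal(semi_center(ce)$b, ce$b, tolerance = 1e-12)
  }
})

test_that("density grids reduce to the component density and integrate to 1", {
  fit <- list(draws = list(sub_mu = matrix(50, 3, 1),
                           sub_sigma2 = matrix(4, 3, 1),
                           sub_p = matrix(1, 3, 1)),
              cfg = list(design = "two_way"))
  class(fit) <- "raterfit"
  g <- density_grid(fit, "theta", from = 30, to = 70, n = 401)
  expect_equal(g$mean, dnorm(g$x, 50, 2), tolerance = 1e-12)
  expect_equal(sum(g$mean) * diff(g$x[1:2]), 1, tolerance = 1e-3)
  expect_equal(g$lower, g$upper, tolerance = 1e-12)  # constant draws
})

test_that("PSM is symmetric with unit diagonal; degenerate cases behave", {
  al <- rbind(c(1L, 1L, 2L), c(1L, 1L, 2L), c(1L, 1L, 2L))
  P <- psm(al)
  expect_true(isSymmetric(P))
  expect_equal(diag(P), rep(1, 3))
  expect_true(all(P %in% c(0, 1)))
  ce <- cluster_estimate(al)
  expect_equal(ce$vi, 0, tolerance = 1e-12)
  expect_equal(rand_index(ce$partition, c(1, 1, 2)), 1)
  # independent uniform two-label allocations: off-diagonal around 0.5
  set.seed(8)
  al2 <- matrix(sample(1:2, 400 * 6, TRUE), 400, 6)
  P2 <- psm(al2)
  off <- P2[upper.tri(P2)]
  expect_true(all(abs(off - 0.5) < 3.5 * sqrt(0.25 / 400)))
})

test_that("the VI point partition is optimal within its candidate set", {
  set.seed(18)
  al <- rbind(matrix(rep(c(1L, 1L, 2L, 2L, 3L), 30), 30, 5, byrow = TRUE),
              matrix(sample(1:3, 20 * 5, TRUE), 20, 5))
  ce <- cluster_estimate(al)
  expect_true(all(ce$vi <= ce$candidate_vi + 1e-12))
  expect_true(isSymmetric(ce$psm))
  expect_true(all(ce$psm >= 0 & ce$psm <= 1))
})

test_that("WAIC identity, duplication invariance and naive-loop agreement", {
  set.seed(3)
  ll <- matrix(rnorm(40 * 15, -2, 0.3), 40, 15)
  w <- waic(ll)
  expect_equal(w$waic, -2 * (w$lppd - w$p_waic), tolerance = 1e-12)
  expect_equal(waic(rbind(ll, ll))$waic, w$waic, tolerance = 1e-10)
  one <- waic(ll[1, , drop = FALSE])
  expect_equal(one$p_waic, 0)
  expect_equal(one$waic, -2 * sum(ll[1, ]))
  # independent naive implementation, point by point (1/T variance)
  lppd <- 0; p <- 0
  for (n in 1:15) {
    lppd <- lppd + log(mean(exp(ll[, n])))
    p <- p + mean((ll[, n] - mean(ll[, n]))^2)
  }
  expect_equal(w$lppd, lppd, tolerance = 1e-8)
  expect_equal(w$p_waic, p, tolerance = 1e-8)
})

test_that("compare_waic orders models and rejects mismatched data", {
  tbl <- suppressWarnings(simulate_ratings("unimodal", seed = 10, I = 30,
                                           J = 8, k = 3))
  fa <- fit_raters(tbl, "BNP", iterations = 300, burnin = 100, thin = 2,
                   seed = 1)
  fb <- fit_raters(tbl, "BP", iterations = 300, burnin = 100, thin = 2,
                   seed = 2)
  tab <- compare_waic(list(BNP = fa, BP = fb))
  expect_equal(tab$delta_waic[1], 0)
  expect_true(all(diff(tab$waic) >= 0))
  other <- suppressWarnings(simulate_ratings("unimodal", seed = 11, I = 30,
                                             J = 8, k = 3))
  fc <- fit_raters(other, "BP", iterations = 300, burnin = 100, thin = 2,
                   seed = 3)
  expect_error(compare_waic(list(a = fa, b = fc)), "same data")
})

test_that("PPC statistics are near zero asymmetry for symmetric fits", {
  tbl <- suppressWarnings(simulate_ratings("unimodal", seed = 12, I = 40,
                                           J = 10, k = 3))
  fit <- fit_raters(tbl, "BNP", iterations = 400, burnin = 150, thin = 2,
                    seed = 4)
  # the Monte-Carlo expected pairwise ICC dominates its lower bound
  set.seed(99)
  mc <- posterior_icc(fit, "pairwise_mc", n_pairs = 100)
  lb <- posterior_icc(fit, "bnp")
  expect_gte(mc$mean, lb$mean - 0.02)
  expect_true(all(mc$values >= 0 & mc$values < 1))

  pp <- ppc_statistics(fit, n_rep = 50)
  expect_equal(pp$statistic, c("t_asym", "t_left"))
  expect_lt(abs(pp$rep_mean[1]), 2)      # asymmetry small on rating scale
  expect_true(all(pp$tail_prob >= 0 & pp$tail_prob <= 1))
  # calibration: observed statistic not in the extreme tail of replicates
  expect_true(pp$tail_prob[1] > 0.01 && pp$tail_prob[1] < 0.99)
})

test_that("recovery metrics compute exact zero/bias cases and scaling", {
  tbl <- suppressWarnings(simulate_ratings("unimodal", seed = 13, I = 20,
                                           J = 6, k = 3))
  tr <- scenario_truth(tbl)
  fit <- fit_raters(tbl, "BNP", iterations = 300, burnin = 100, thin = 2,
                    seed = 5, truth = tr)
  # exact-recovery limit: posterior means replaced by the truth
  fit0 <- fit
  fit0$draws$theta <- matrix(tr$theta, fit$n_draws, 20, byrow = TRUE)
  fit0$draws$b <- matrix(tr$b, fit$n_draws, 6, byrow = TRUE)
  rm0 <- recovery_metrics(fit0, tr)
  expect_equal(rm0$rmse[rm0$parameter == "theta"], 0)
  expect_equal(rm0$mae[rm0$parameter == "b"], 0)
  # constant +1 bias gives MAE = RMSE = 1, standardized by scale center
  fit1 <- fit
  fit1$draws$theta <- matrix(tr$theta + 1, fit$n_draws, 20, byrow = TRUE)
  rm1 <- recovery_metrics(fit1, tr)
  th <- rm1[rm1$parameter == "theta", ]
  expect_equal(th$rmse, 1)
  expect_equal(th$mae, 1)
  expect_equal(th$s_rmse, 1 / 50.5)   # (1 + 100) / 2
})
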