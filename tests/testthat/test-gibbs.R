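test_that("config validates variant-implied truncations", {
  expect_equal(rater_config(variant = "BP")$R_subj, 1L)
  expect_equal(rater_config(variant = "BP")$R_rater, 1L)
  expect_equal(rater_config(variant = "BSP", R_subj = 10)$R_rater, 1L)
  expect_gt(rater_config(variant = "BSP", R_subj = 10)$R_subj, 1L)
  expect_error(rater_config(iterations = 100, burnin = 200), "iterations")
})

test_that("initial state honours the stated initialization contract", {
  tbl <- toy_ratings()
  cfg <- desk_cfg(variant = "BNP", scale_low = 1, scale_high = 50)
  st <- init_state(tbl, cfg)
  # theta starts at each subject's mean observed rating
  expect_equal(st$theta, c(mean(c(30, 35)), mean(c(12, 18))))
  expect_true(all(st$tau > 0))
  expect_true(all(st$c >= 1 & st$c <= cfg$R_subj))
  expect_equal(sum(st$p), 1, tolerance = 1e-12)
  # single-rating subject inits at that rating
  one <- ratings(data.frame(subject = c("a", "b"), rater = c("x", "y"),
                            rating = c(42, 7)), 1, 50)
  expect_equal(init_state(one, cfg)$theta, c(42, 7))
  # zero-rating subjects are impossible by construction, but guard anyway
  expect_error(init_state(structure(one, subjects = c("a", "b", "ghost")),
                          cfg), "zero ratings")
})

test_that("sweeps preserve invariants and are seed-reproducible", {
  tbl <- suppressWarnings(simulate_ratings("bimodal", seed = 2, I = 25,
                                           J = 8, k = 3))
  cfg <- desk_cfg(variant = "BNP", R_subj = 6, R_rater = 4)
  set.seed(5)
  st <- init_state(tbl, cfg)
  d <- raterdpm:::.dat_view(tbl)
  for (s in 1:30) {
    st <- gibbs_sweep(st, tbl, cfg)
    expect_equal(sum(st$p), 1, tolerance = 1e-12)
    expect_equal(sum(st$q), 1, tolerance = 1e-12)
    expect_true(all(st$tau > 0))
    expect_true(all(st$c >= 1 & st$c <= cfg$R_subj))
    expect_true(all(st$z >= 1 & st$z <= cfg$R_rater))
    expect_true(all(st$sub_atoms$sigma2 > 0))
  }
  set.seed(9); a <- gibbs_sweep(init_state(tbl, cfg), tbl, cfg)
  set.seed(9); b <- gibbs_sweep(init_state(tbl, cfg), tbl, cfg)
  expect_identical(a, b)
})

test_that("BP truncation pins every allocation to one cluster", {
  tbl <- suppressWarnings(simulate_ratings("unimodal", seed = 3, I = 20,
                                           J = 6, k = 3))
  cfg <- desk_cfg(variant = "BP")
  st <- init_state(tbl, cfg)
  for (s in 1:10) {
    st <- gibbs_sweep(st, tbl, cfg)
    expect_equal(st$c, rep(1L, 20))
    expect_equal(st$z, rep(1L, 6))
    expect_equal(st$p, 1)
  }
})

test_that("successive-conditional simulation reproduces prior marginals", {
  # Geweke-style calibration: alternating Gibbs sweeps with data
  # re-simulation must leave the prior invariant. Quantiles (25/50/75%)
  # of seven scalar functionals are compared against direct prior draws,
  # in units of the prior IQR. Tolerance 0.25 on the median absolute
  # deviation was calibrated from the Monte-Carlo noise of this chain
  # length; the stick/concentration bias this test is designed to catch
  # sits well above it.
  set.seed(20260901)
  I <- 20; J <- 8; k <- 3
  des <- generate_design(I, J, k)
  si <- rep(seq_len(I), each = k); ri <- as.integer(t(des))
  d <- list(si = si, ri = ri, y = numeric(length(si)),
            I = I, J = J, N = length(si))
  cfg <- rater_config(variant = "BNP", R_subj = 5, R_rater = 4,
                      iterations = 10, burnin = 1, thin = 1,
                      scale_low = 0, scale_high = 10,
                      hyper = list(prec0_loc = 1, a0 = 2, b0 = 2))
  fn <- function(st) {
    sm <- mixture_moments(st$p, st$sub_atoms$mu, st$sub_atoms$sigma2)
    bm <- mixture_moments(st$q, st$rat_atoms$beta, st$rat_atoms$omega2)
    c(mean_theta = unname(sm["mean"]), var_theta = unname(sm["var"]),
      mean_b = unname(bm["mean"]), var_b = unname(bm["var"]),
      mean_tau = sum(st$q * st$rat_atoms$eta), alpha_G = st$alpha_G,
      alpha_H = st$alpha_H)
  }
  nchain <- 4L; M <- 2000L; burn <- 200L
  chain <- NULL
  for (ch in seq_len(nchain)) {
    st <- raterdpm:::.draw_state_prior(d, cfg)
    vals <- matrix(NA_real_, M, 7L)
    for (m in seq_len(M)) {
      y <- raterdpm:::.simulate_data_from_state(st, d)
      st <- raterdpm:::.sweep_twoway(st, y, d, cfg)
      vals[m, ] <- fn(st)
    }
    chain <- rbind(chain, vals[-seq_len(burn), ])
  }
  colnames(chain) <- names(fn(st))
  prior <- t(replicate(20000, fn(raterdpm:::.draw_state_prior(d, cfg))))
  qs <- c(0.25, 0.5, 0.75)
  for (nm in colnames(chain)) {
    qp <- quantile(prior[, nm], qs)
    qc <- quantile(chain[, nm], qs)
    iqr <- diff(quantile(prior[, nm], c(0.25, 0.75)))
    dev <- abs(qc - qp) / iqr
    expect_lt(median(dev), 0.25, label = paste0(nm, " median q-dev"))
    expect_lt(max(dev), 0.4, label = paste0(nm, " max q-dev"))
  }
})

test_that("fits are bit-reproducible and seeds give overlapping posteriors", {
  tbl <- suppressWarnings(simulate_ratings("unimodal", seed = 8, I = 40,
                                           J = 10, k = 3))
  f1 <- fit_raters(tbl, "BNP", iterations = 400, burnin = 100, thin = 2,
                   seed = 7)
  f2 <- fit_raters(tbl, "BNP", iterations = 400, burnin = 100, thin = 2,
                   seed = 7)
  expect_identical(f1$draws$scalars, f2$draws$scalars)
  f3 <- fit_raters(tbl, "BNP", iterations = 600, burnin = 200, thin = 2,
                   seed = 99)
  t1 <- tidy(f1); t3 <- tidy(f3)
  for (tm in c("var_theta", "mean_theta")) {
    a <- t1[t1$term == tm, ]; b <- t3[t3$term == tm, ]
    expect_true(a$conf.low <= b$conf.high && b$conf.low <= a$conf.high,
                label = paste("overlapping intervals for", tm))
  }
})
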