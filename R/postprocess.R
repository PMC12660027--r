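#' Semi-center a raw draw
#'
#' Parameter-expansion transform restoring identifiability: the rater-bias
#' mixture mean `mb = sum(q * beta)` is subtracted from every bias quantity
#' and added to every true-score quantity, so the bias mixture mean becomes
#' exactly zero while every record's linear predictor `theta + b` (hence
#' the likelihood) is unchanged.
#'
#' @param draw list with elements `theta`, `b`, `sub_atoms` (`mu`,
#'   `sigma2`), `rat_atoms` (`beta`, ...), `p`, `q`
#' @return the centered draw, same structure
#' @export
semi_center <- function(draw) {
  mb <- sum(draw$q * draw$rat_atoms$beta)
  draw$b <- draw$b - mb
  draw$rat_atoms$beta <- draw$rat_atoms$beta - mb
  draw$theta <- draw$theta + mb
  draw$sub_atoms$mu <- draw$sub_atoms$mu + mb
  draw
}

#' Pointwise posterior of a mixture density on a grid
#'
#' Evaluates the finite-mixture density implied by each retained draw on a
#' dense grid of equally spaced points and summarizes each point by its
#' posterior mean and equal-tailed quantile band.
#'
#' @param fit a `raterfit`
#' @param target `"theta"` (subject true score), `"b"` (rater bias,
#'   two-way fits) or `"error"` (per-rating error, one-way fits)
#' @param from,to grid bounds; defaults cover the posterior atoms
#' @param n number of grid points
#' @param conf_level band level
#' @return tibble with columns `x`, `mean`, `lower`, `upper`
#' @export
density_grid <- function(fit, target = c("theta", "b", "error"),
                         from = NULL, to = NULL, n = 128L,
                         conf_level = 0.95) {
  stopifnot(inherits(fit, "raterfit"))
  target <- match.arg(target)
  dr <- fit$draws
  parts <- switch(target,
    theta = list(mu = dr$sub_mu, s2 = dr$sub_sigma2, w = dr$sub_p),
    b = {
      if (fit$cfg$design == "one_way") stop("no rater-bias block in a one-way fit")
      list(mu = dr$rat_beta, s2 = dr$rat_omega2, w = dr$rat_q)
    },
    error = {
      if (fit$cfg$design != "one_way") stop("error density requires a one-way fit")
      list(mu = dr$err_delta, s2 = dr$err_psi2, w = dr$err_p)
    })
  if (is.null(from) || is.null(to)) {
    sdm <- sqrt(max(parts$s2))
    from <- from %||% (min(parts$mu) - 3 * sdm)
    to <- to %||% (max(parts$mu) + 3 * sdm)
  }
  x <- seq(from, to, length.out = n)
  T_ <- nrow(parts$mu)
  dens <- matrix(0, T_, n)
  for (t in seq_len(T_)) {
    w <- parts$w[t, ]
    keep <- w > 1e-12
    dens[t, ] <- colSums(w[keep] *
      dnorm(matrix(x, sum(keep), n, byrow = TRUE),
            parts$mu[t, keep], sqrt(parts$s2[t, keep])))
  }
  a <- (1 - conf_level) / 2
  tibble::tibble(x = x, mean = colMeans(dens),
                 lower = apply(dens, 2L, quantile, a),
                 upper = apply(dens, 2L, quantile, 1 - a))
}

#' Posterior similarity matrix from allocation draws
#'
#' @param alloc draws-by-items integer matrix of cluster allocations
#' @return symmetric matrix of pairwise co-clustering frequencies with unit
#'   diagonal
#' @export
psm <- function(alloc) {
  stopifnot(is.matrix(alloc), nrow(alloc) >= 2L)
  n <- ncol(alloc)
  P <- matrix(0, n, n)
  for (t in seq_len(nrow(alloc))) {
    a <- alloc[t, ]
    P <- P + (outer(a, a, "=="))
  }
  P <- P / nrow(alloc)
  diag(P) <- 1
  P
}

# Wade-Ghahramani lower bound of the posterior expected VI of partition cl.
.vi_lower_bound <- function(cl, P) {
  n <- length(cl)
  same <- outer(cl, cl, "==")
  (sum(log2(rowSums(same))) + sum(log2(rowSums(P))) -
     2 * sum(log2(rowSums(same * P)))) / n
}

#' Point-estimate partition by variation-of-information minimization
#'
#' Summarizes the posterior over partitions by the candidate minimizing the
#' posterior-expected variation of information lower bound. Candidates are
#' the sampled partitions plus average-linkage cuts of the posterior
#' similarity matrix at every cluster count up to `max_k`.
#'
#' @param fit a `raterfit`, or a draws-by-items allocation matrix
#' @param which `"subject"`, `"rater"` or `"error"` (ignored when `fit` is
#'   a matrix)
#' @param max_k largest dendrogram cut considered
#' @return a `cluster_estimate` list: `psm`, `partition` (relabelled
#'   1..K), `vi` (its expected-VI lower bound), `candidate_vi` (all
#'   candidates' scores)
#' @export
cluster_estimate <- function(fit, which = c("subject", "rater", "error"),
                             max_k = 12L) {
  if (inherits(fit, "raterfit")) {
    which <- match.arg(which)
    alloc <- switch(which,
      subject = fit$draws$c,
      rater = {
        if (fit$cfg$design == "one_way") stop("no rater block in one-way fit")
        fit$draws$z
      },
      error = {
        if (fit$cfg$design != "one_way") stop("error clusters need a one-way fit")
        fit$draws$dn
      })
  } else {
    alloc <- fit
  }
  P <- psm(alloc)
  n <- ncol(P)
  cand <- unique(as.data.frame(alloc))
  cand <- lapply(seq_len(nrow(cand)), function(i) as.integer(cand[i, ]))
  hc <- hclust(as.dist(1 - P), method = "average")
  for (k in seq_len(min(max_k, n))) cand <- c(cand, list(cutree(hc, k = k)))
  scores <- vapply(cand, .vi_lower_bound, numeric(1L), P = P)
  best <- which.min(scores)
  part <- as.integer(factor(cand[[best]]))
  structure(list(psm = P, partition = part, vi = scores[best],
                 candidate_vi = scores), class = "cluster_estimate")
}

#' @export
print.cluster_estimate <- function(x, ...) {
  cat(sprintf("<cluster_estimate: %d items, %d clusters, expected VI bound %.4f>\n",
              length(x$partition), max(x$partition), x$vi))
  invisible(x)
}

#' Adjusted-free Rand index between two partitions
#'
#' @param a,b integer partitions of the same items
#' @return Rand index in `[0, 1]`
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  sa <- outer(a, a, "==")
  sb <- outer(b, b, "==")
  ut <- upper.tri(sa)
  mean(sa[ut] == sb[ut])
}

#' Watanabe-Akaike information criterion
#'
#' From the stored pointwise log-likelihood matrix:
#' `lppd = sum_n log mean_t exp(ll[t, n])` (log-sum-exp stabilized),
#' `p_waic = sum_n var_t(ll[t, n])`, `waic = -2 * (lppd - p_waic)`.
#' The variance over draws uses the `1/T` normalization, which makes the
#' criterion exactly invariant under duplicating the draws.
#'
#' @param fit a `raterfit`, or a draws-by-observations log-likelihood matrix
#' @return list with `waic`, `lppd`, `p_waic`, `elpd`
#' @export
waic <- function(fit) {
  ll <- if (inherits(fit, "raterfit")) fit$draws$loglik else fit
  stopifnot(is.matrix(ll))
  T_ <- nrow(ll)
  m <- apply(ll, 2L, max)
  lppd <- sum(m + log(colMeans(exp(sweep(ll, 2L, m)))))
  p_waic <- sum(colMeans(ll^2) - colMeans(ll)^2)
  if (T_ == 1L) p_waic <- 0
  elpd <- lppd - p_waic
  list(waic = -2 * elpd, lppd = lppd, p_waic = p_waic, elpd = elpd)
}

#' WAIC comparison table across fitted models
#'
#' @param ... named `raterfit` objects fitted to the same data
#' @return tibble with `model`, `waic`, `p_waic`, `delta_waic` (difference
#'   to the best-fitting model)
#' @export
compare_waic <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1L]]) &&
      !inherits(fits[[1L]], "raterfit")) {
    fits <- fits[[1L]]
  }
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1L), "raterfit")))
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) f$cfg$variant, character(1L))
  }
  hashes <- vapply(fits, function(f) f$manifest$data_hash, character(1L))
  if (length(unique(hashes)) > 1L) {
    stop("fits were not run on the same data (data hashes differ)")
  }
  ws <- purrr::map_dfr(names(fits), function(nm) {
    w <- waic(fits[[nm]])
    tibble::tibble(model = nm, waic = w$waic, p_waic = w$p_waic)
  })
  ws$delta_waic <- ws$waic - min(ws$waic)
  dplyr::arrange(ws, .data$waic)
}

#' Posterior predictive discrepancy statistics
#'
#' For each of `n_rep` retained draws, a replicated data set is simulated
#' from the posterior predictive and two discrepancy statistics are
#' computed: central asymmetry `T_asym = (q3 - q2) - (q2 - q1)` (quartiles)
#' and left-tail weight `T_left = q2 - q05` (median minus 5th percentile).
#' The tail probability is the fraction of replicates with a statistic at
#' least as large as the observed one.
#'
#' @param fit a `raterfit`
#' @param n_rep number of replicated data sets (capped at the number of
#'   retained draws)
#' @return tibble with one row per statistic: `statistic`, `observed`,
#'   `rep_mean`, `tail_prob`, plus a `replicates` list-column
#' @export
ppc_statistics <- function(fit, n_rep = 200L) {
  stopifnot(inherits(fit, "raterfit"))
  d <- .dat_view(fit$data)
  n_rep <- min(n_rep, fit$n_draws)
  idx <- round(seq(1L, fit$n_draws, length.out = n_rep))
  t_asym <- function(y) {
    q <- quantile(y, c(0.25, 0.5, 0.75), names = FALSE)
    (q[3L] - q[2L]) - (q[2L] - q[1L])
  }
  t_left <- function(y) {
    q <- quantile(y, c(0.05, 0.5), names = FALSE)
    q[2L] - q[1L]
  }
  reps <- vapply(idx, function(t) {
    y <- .replicate_data(fit, t, d)
    c(t_asym(y), t_left(y))
  }, numeric(2L))
  obs <- c(t_asym(d$y), t_left(d$y))
  tibble::tibble(
    statistic = c("t_asym", "t_left"),
    observed = obs,
    rep_mean = rowMeans(reps),
    tail_prob = c(mean(reps[1L, ] >= obs[1L]), mean(reps[2L, ] >= obs[2L])),
    replicates = list(reps[1L, ], reps[2L, ]))
}

# Simulate one replicated data set from draw t of the posterior predictive.
.replicate_data <- function(fit, t, d) {
  dr <- fit$draws
  if (fit$cfg$design == "one_way") {
    mu <- dr$theta[t, d$si] + dr$err_delta[t, dr$dn[t, ]]
    return(rnorm(d$N, mu, sqrt(dr$err_psi2[t, dr$dn[t, ]])))
  }
  mu <- dr$theta[t, d$si] + dr$b[t, d$ri]
  ystar <- rnorm(d$N, mu, 1 / sqrt(dr$tau[t, d$ri]))
  if (fit$cfg$likelihood == "ordinal") {
    zeta <- dr$zeta[t, ]
    return(1 + rowSums(outer(ystar, zeta, ">")))
  }
  ystar
}

#' Recovery metrics against simulation truth
#'
#' RMSE and MAE of posterior means against the generating truth, per
#' parameter block, with standardized variants: location-type blocks are
#' divided by the rating-scale center, the others by their true value.
#'
#' @param fit a `raterfit` carrying a `truth` element (see
#'   [simulate_ratings()]), or pass `truth` explicitly
#' @param truth a `scenario_truth` list
#' @return tibble with `parameter`, `rmse`, `mae`, `s_rmse`, `s_mae`
#' @export
recovery_metrics <- function(fit, truth = fit$truth) {
  stopifnot(inherits(fit, "raterfit"), !is.null(truth))
  center <- .scale_center(fit$cfg)
  s <- posterior_draws(fit)
  rows <- list()
  add <- function(name, est, tru, scale_by) {
    err <- est - tru
    rmse <- sqrt(mean(err^2)); mae <- mean(abs(err))
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      parameter = name, rmse = rmse, mae = mae,
      s_rmse = rmse / scale_by, s_mae = mae / scale_by)
  }
  add("theta", colMeans(fit$draws$theta), truth$theta, center)
  if (fit$cfg$design != "one_way" && !is.null(truth$b)) {
    add("b", colMeans(fit$draws$b), truth$b, center)
    if (!is.null(truth$tau) && !all(is.na(fit$draws$tau))) {
      add("tau", colMeans(fit$draws$tau), truth$tau, mean(truth$tau))
    }
  }
  for (nm in c("var_theta", "var_b", "mean_residual_var", "icc_e")) {
    tv <- truth[[nm]]
    if (!is.null(tv) && nm %in% names(s) && !all(is.na(s[[nm]]))) {
      add(nm, mean(s[[nm]]), tv, abs(tv))
    }
  }
  dplyr::bind_rows(rows)
}
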