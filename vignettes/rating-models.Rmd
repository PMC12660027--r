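---
title: "Bayesian nonparametric models for rating data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian nonparametric models for rating data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raterdpm)
```

## The measurement model

A rater $j$ scores a subject $i$ on a bounded continuous scale. The
observed rating decomposes additively,

$$y_{ij} = \theta_i + b_j + \varepsilon_{ij}, \qquad
  \varepsilon_{ij} \sim N(0,\ \tau_j^{-1}),$$

where $\theta_i$ is subject $i$'s latent true score (the target of the
rating procedure), $b_j$ is rater $j$'s systematic bias
(severity/leniency), and $\tau_j$ is rater $j$'s reliability — the
precision of their ratings around $\theta_i + b_j$. The design is crossed
and in general unbalanced: each subject is scored by a small subset of
raters, and workloads differ across raters.

Instead of assuming a single normal population for subjects and another
for raters, both sets of individual effects receive Dirichlet process
mixture (DPM) priors:

* $\theta_i \sim N(\mu_{c_i}, \sigma^2_{c_i})$, with the atoms
  $(\mu_n, \sigma^2_n)$ drawn from a base measure $G_0$ and subjects
  allocated to components by stick-breaking weights;
* $(b_j, \tau_j)$ likewise: $b_j \sim N(\beta_{z_j}, \omega^2_{z_j})$ and
  $\tau_j \sim \mathrm{Gamma}(1 + \nu_{z_j},\ \text{mean } \eta_{z_j})$,
  with four-dimensional rater atoms
  $(\beta_k, \omega^2_k, \nu_k, \eta_k)$ from $H_0$.

The almost-sure discreteness of the DP gives positive probability of
ties, so subjects (and, independently, raters) cluster without fixing the
number of components. Truncated stick-breaking
($p_r = v_r \prod_{s<r}(1 - v_s)$, $v_r \sim \mathrm{Beta}(1, \alpha)$,
last fraction forced to one) makes a blocked Gibbs sampler possible;
defaults truncate at 30 subject and 20 rater components, far above the
occupied-cluster counts seen at the problem sizes this package targets,
and both truncations are configurable. Setting both truncations to one
recovers the fully parametric model (the `BP` variant); truncating only
the rater mixture gives the semiparametric `BSP` variant, appropriate
when a small rater panel cannot support inference about rater
subpopulations.

### Reliability parametrization

Gamma components for $\tau$ are stored as (shape, mean) rather than
(shape, rate): the mean $\eta_k$ is directly interpretable as the
component's typical reliability. The component shape is shifted,
$\tau \mid k \sim \mathrm{Gamma}(1 + \nu_k, \cdot)$ with $\nu_k > 0$, so
that the residual variance $1/\tau$ always has a finite component mean

$$E[1/\tau \mid k] = \frac{1 + \nu_k}{\nu_k\,\eta_k},$$

which the population ICC below requires. The unshifted variant remains
available in `dm_gamma_shape()` and `reliability_moments()` for
completeness, with an explicit error when a component shape does not
exceed one.

## Intraclass correlation family

With mixture moments $\bar\sigma^2_\theta$ (true-score variance),
$\bar\omega^2_b$ (bias variance) and
$\bar\lambda = \sum_k q_k E[1/\tau \mid k]$ (mean residual variance), the
package computes:

* `icc_parametric(vt, vb, rv)` — the classical proportion of rating
  variance due to subjects, $v_\theta / (v_\theta + v_b + \sigma^2_\varepsilon)$;
* `icc_pairwise(vt, vb, tau_j, tau_jp)` — the conditional correlation of
  two specific raters' ratings of a random subject;
* `icc_conditional_bnp()` — the same functional with full mixture
  variances plugged in (reduces to the parametric pairwise index under
  single components);
* `icc_E_bnp(vt, vb, mrv)` — the population index
  $\bar\sigma^2_\theta / (\bar\sigma^2_\theta + \bar\omega^2_b + \bar\lambda)$.
  Because $x \mapsto 1/\sqrt{D + x}$ is convex, Jensen's inequality makes
  this a certified lower bound of the expected pairwise ICC over random
  rater pairs; the test suite re-verifies the bound on randomized
  mixtures. The expected pairwise ICC itself has no closed form; a
  Monte-Carlo version with a user-set pair budget is available through
  `posterior_icc(fit, "pairwise_mc")`, but `icc_E` is the default report.

All indices are non-negative and below one by construction; none can
express negative inter-rater correlation.

For one-way designs (rater identity unknown, so each "rater" effectively
scores one subject) the model reduces to $y_{ij} = \theta_i + e_{ij}$
with a DPM over per-rating errors $(\delta_l, \psi^2_l)$. Errors are
allocated per rating, not per rater, because rater identity is not
identifiable there. The one-way ICC is exact:
$v_\theta / (v_\theta + v_e)$ with $v_e$ the full error-mixture variance.

## Posterior computation

A blocked Gibbs sweep updates, in order: subject true scores; subject
allocations; subject atoms; subject stick fractions; rater biases and
reliabilities; rater allocations; rater atoms; rater sticks; both DP
concentrations; and the base-measure hyperparameters. All conditionals
are conjugate except the gamma shapes $\nu_k$, which are updated by a
derivatives-matching (D-M) gamma approximation: a
$\mathrm{Gamma}(\hat a, \hat b)$ density is fitted so that the first and
second derivatives of its log density equal those of the true
unnormalized full conditional at the current approximating mean, and the
matching point is iterated to the fitted mean (tolerance $10^{-8}$, at
most 10 iterations; non-convergence falls back to the last iterate with a
warning and a `dm_failures` diagnostic count — never silently). The
shifted-shape target uses the same scheme with the shape offset by one.
Because the D-M draw is not Metropolis-corrected, reliability-related
posteriors carry the approximation's (small, well-documented) bias; the
prior-reproduction test below bounds it in practice.

### Numerical choices worth knowing

* **Stick fractions and concentrations.** Fractions are drawn through
  their two underlying gamma variables so that $\log(1 - v_r)$ is
  available exactly even when $v_r$ is numerically one (the second shape
  can be far below one). The concentration update
  $\alpha \sim \mathrm{Gamma}(a + R - 1,\ b - \sum_{r<R} \log(1 - v_r))$
  consumes that exact quantity. Clamping $v_r$ instead provably biases
  $\alpha$ upward — a successive-conditional simulation catches it — so
  the package does not clamp.
* **Base measures.** Location means and the means of precision-type
  components carry conjugate hyperpriors (normal and inverse-gamma, with
  the vague constants 0.005 and the location prior centered at the
  rating-scale center). The gamma *shapes* of the base measure are fixed
  constants (default 3): refresh draws for empty clusters then have
  tolerable tails, so mixture-variance functionals remain stable. The
  mean of the reliability-shape component ($\nu$'s base) is deliberately
  *not* given a hyperprior: it is only weakly identified, and letting it
  track the atoms creates an absorbing regime in which $\nu \to \infty$
  collapses all reliabilities onto their component mean.
* **Floors and guards.** Variances are floored at $10^{-10}$; allocation
  probabilities go through log-sum-exp; weights are renormalized to an
  exact unit sum.
* **Identifiability.** The sampler runs non-centered; every retained draw
  is *semi-centered* afterwards: the bias-mixture mean
  $\bar b = \sum_k q_k \beta_k$ is subtracted from all bias quantities
  and added to all true-score quantities. The per-record linear predictor
  is exactly invariant and the centered bias mixture has mean exactly
  zero. Only the location is centered — scales are untouched. No
  label-switching relabeling is attempted: every reported target
  (densities, moments, ICCs, similarity matrices) is label-invariant, and
  raw atom traces are non-identified.
* **Seeding.** One integer seed passed to `fit_raters()` drives the whole
  run through R's own generator; replicate seeds in the test bed are
  small integer offsets of a master seed. (R provides no counter-based
  generator; per-fit `set.seed()` with distinct offsets is the standard R
  idiom and keeps every fit independently reproducible.)

### Ordinal (coarsened) ratings

Coarse ratings are modeled through an underlying normal variable: the
observed category is $c$ when $y^*_{ij} \in (\zeta_{c-1}, \zeta_c]$, with
thresholds shared across raters (a nonparametric heteroscedastic ordered
probit). The sampler alternates truncated-normal augmentation of $y^*$,
the continuous sweep on the latent ratings, and a uniform conditional
update of the free thresholds. Two interior thresholds must be fixed for
identifiability when $C \ge 3$; with a coarsened table produced by
`coarsen()` the generating cutoffs are known and the outer two are fixed
at their true values while middle ones are estimated — the pattern real
coarse-rating analyses use. With $C = 2$ the residual variances cannot be
identified either, so all reliabilities are fixed at one. Categories are
right-closed, matching `coarsen()`'s convention that a value exactly at a
cutoff falls in the lower category. Post-processing applies a *double*
centering (subject and bias mixture means both zeroed, the total shift
absorbed into the thresholds), leaving every cell probability exactly
invariant. ICCs computed from ordinal fits are polychoric correlations
between latent ratings, and `icc_e` their lower bound.

## Post-processing and diagnostics

* **Density grids** — each retained draw's finite mixture evaluated on an
  equally spaced grid; pointwise (not simultaneous) mean and equal-tailed
  quantile bands.
* **Clustering** — the posterior similarity matrix (PSM) of co-allocation
  frequencies, and a point partition minimizing the Wade–Ghahramani lower
  bound of the posterior-expected variation of information over a
  deterministic candidate set: all sampled partitions plus average-linkage
  PSM dendrogram cuts. The chosen partition is optimal within that set by
  construction; a full greedy search is deliberately out of scope.
* **WAIC** — $-2(\mathrm{lppd} - p_\mathrm{waic})$ from pointwise
  log-likelihoods stored during the run, with the $1/T$ variance
  normalization so the criterion is exactly invariant under duplicating
  draws; `compare_waic()` refuses fits whose data hashes differ.
* **Posterior predictive checks** — replicated data sets from retained
  draws, summarized by a quartile-based central-asymmetry statistic
  $T_\mathrm{asym} = (q_3 - q_2) - (q_2 - q_1)$ and a left-tail weight
  $T_\mathrm{left} = q_2 - q_{0.05}$. These two concrete formulas are this
  package's committed definitions, built from the named quartile and
  5th-percentile quantities.
* **Recovery metrics** — RMSE and MAE of posterior means against
  generating truth; standardized variants divide location-type blocks by
  the rating-scale center and all others by their true value.

## The synthetic test bed

`default_scenarios()` fixes three generative processes on a 1–100 scale
with 300 subjects, 50 raters and 2 (or 5) ratings per subject; these
presets are the package's committed study conditions, and every number
lives in that one function:

* **unimodal** — one subject component $N(55, 6^2)$ and one rater
  component ($b \sim N(0, 1.5^2)$, $\nu = 5$, $\eta = 0.1$): the
  correctly specified parametric case.
* **bimodal** — two equally weighted subject proficiency clusters
  ($N(44, 6^2)$, $N(66, 6^2)$, about two mixture SDs apart) and two rater
  clusters: 60% slightly lenient and reliable ($+1.5$, $\omega^2 = 1$,
  $\nu = 6$, $\eta = 0.2$), 40% more severe and less reliable ($-3$,
  $\omega^2 = 2.25$, $\nu = 3$, $\eta = 0.05$).
* **multimodal** — three poorly separated skew-normal subject clusters
  (locations 72/58/38, negative slants) yielding a clearly negatively
  skewed true-score density, and three rater clusters spanning severity
  and reliability.

Generated ratings may fall outside the nominal scale; they are kept
unclipped (the model itself is unbounded — scale bounds validate real
data only) and counted in the attached truth. The generator emulates
unbalanced crossed designs with clustered effects and heteroscedastic
raters; it does **not** emulate rater drift over time, covariate-driven
heterogeneity, missing-data mechanisms, or repeated ratings of the same
pair, so passing recovery tests demonstrate correctness under the stated
mixture conditions, not robustness to those real-data features.

Skew-normal components are sampled by the standard
(location, scale, slant) construction from two normals, with closed-form
moments used for the recorded truth; the truth's ICC is computed with
the same moment code the posterior uses, which ties generator and
estimator together and is itself under test.

## Problem sizes used by the checks

The packaged checks run at desk scale, chosen so the whole suite stays
comfortably inside a coffee break on one CPU: recovery and model-ranking
experiments use $I = 150$, $J = 30$, five ratings per subject, 2,000
iterations (burn-in 700, thinning 5) with 20 bimodal, 10 multimodal and 6
unimodal replicates; the prior-reproduction (successive-conditional)
check runs four chains of 2,000 sweeps on $I = 20$, $J = 8$; clustering
recovery uses a strongly separated bimodal arm at $I = 80$, $J = 16$. A
production analysis would rather use the `fit_raters()` defaults (80,000
iterations, 20,000 burn-in, thinning 60) and the preset sample sizes.

## Known limitations

* The expected pairwise ICC is only available by Monte-Carlo; `icc_e` is
  a lower bound, typically tight at realistic reliability levels.
* The D-M shape update is an uncorrected approximation; its residual
  bias is below the Monte-Carlo resolution of the packaged
  prior-reproduction test but is not exactly zero.
* Reliability-shape components are a priori bounded away from extreme
  values (fixed base mean 3), so reliability clusters tighter than a
  coefficient of variation of roughly 15–20% are shrunk toward that
  ceiling.
* Mixed designs (some raters identified, some anonymous), covariates,
  more than two crossed identities, and rater-specific thresholds in the
  ordinal model are out of scope.
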