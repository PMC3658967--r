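---
title: "Risk prediction in clustered data: methods behind clustpred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk prediction in clustered data: methods behind clustpred}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Clinical prediction models are routinely developed on data in which patients
are clustered — within hospitals, wards, or individual treating physicians.
Patients of the same physician resemble each other beyond what their
measured characteristics explain, so a standard logistic regression that
ignores the clustering and a random-intercept (multilevel) logistic
regression give different coefficient estimates. For *etiologic* questions
the consequences of ignoring clustering are well understood; for
*prediction* the question is different: which model produces more accurate
absolute risks, and does the answer depend on whether performance is judged
pooled over all patients ("overall") or separately within each cluster?

`clustpred` implements a Monte-Carlo simulation framework to answer this. It
generates clustered populations with a known latent center effect, draws
study samples the way multicenter studies collect data (centers first, then
patients), develops both models, computes risks three ways, and evaluates
overall and within-cluster discrimination and calibration.

## Models and risk calculations

The outcome $Y_{ij} \in \{0,1\}$ of patient $i$ in cluster $j$ is modeled
with six predictors $x_{1} \ldots x_{6}$:

* **Standard model** — ordinary ML logistic regression,
  $\operatorname{logit} P(Y_i = 1) = \hat\alpha_{std} + \sum_m x_{im}\hat\beta_{std,m}$.
* **Random-intercept model** — logistic GLMM with a cluster intercept
  $u_{0j} \sim N(0, \sigma^2_{u0})$, fitted by maximizing the marginal
  likelihood.

From the random-intercept model two risk calculations are defined:

* **marginal**: fixed effects only,
  $\operatorname{logit} p = \hat\alpha_{RE} + \sum_m x_{im}\hat\beta_{RE,m}$ —
  usable for patients of clusters never seen at development;
* **conditional**: fixed effects *plus* the cluster's empirical-Bayes
  intercept $\hat u_{0j}$ — defined only within development clusters, so
  `predict_conditional()` refuses unseen cluster ids rather than silently
  substituting zero.

## Performance battery

For any risk vector against observed outcomes, `evaluate_performance()`
assembles:

* **c-index** (Harrell): probability an event patient outranks a non-event
  patient; ties credited 0.5; computed with midranks ($O(n\log n)$) and
  validated in the tests against explicit pair counting.
* **within-cluster c-index**: unweighted mean of per-cluster c-indices over
  clusters with both outcome classes (clusters without outcome variation are
  excluded and counted). The companion "SD" is the between-cluster SD of the
  per-cluster values. Because a cluster-constant shift cannot reorder
  patients within a cluster, the marginal and conditional calculations have
  identical within-cluster c — only overall discrimination can benefit from
  cluster effects.
* **calibration-in-the-large**: intercept of an outcome-only logistic model
  with the linear predictor as offset (0 is ideal).
* **calibration slope**: coefficient of the linear predictor in a logistic
  recalibration (1 is ideal; below 1 indicates overfitting).
* **within-cluster calibration**: mixed-effect recalibration models. For
  calibration-in-the-large, `y ~ 1 + (1 | cluster)` with the linear
  predictor as offset; for the slope, `y ~ lp + (1 | cluster) + (0 + lp | cluster)`
  with independent (diagonal) random effects. Reported as the fixed effect
  (average within-cluster value) and the random-effect SD (between-cluster
  spread). The ML score equations guarantee the standard model's apparent
  *overall* calibration is exactly (0, 1); the analogous exact statement
  within clusters holds for the conditional calculation, whose
  calibration-in-the-large random-effect SD is estimated at the boundary
  (0) on development data.

## Data-generating process

A source population has 100 centers. Sizes are Poisson with center-specific
means $\exp(z_j)$, $z_j \sim N(5.7, 0.3^2)$ (median size
$\approx e^{5.7} = 299$; zero draws are redrawn). Three continuous
predictors are $N(0, sd)$ with sd 0.2, 0.4, 1; three binary predictors have
incidences 0.2, 0.3, 0.4; all true coefficients are 1. The center effect
$u_{0j} \sim N(0, \sigma^2_{u0})$ with
$\sigma^2_{u0} = \rho\,(\pi^2/3)/(1-\rho)$ for a target latent-scale ICC
$\rho$ (5% → 0.173, 15% → 0.581, 30% → 1.410). Outcomes are drawn by
comparing a uniform deviate with the true risk, $Y = 1 \iff U \le P(Y)$.

Tunable parameters (all in `scenario_config()`):

| parameter | default | meaning |
|---|---|---|
| `icc` | 0.05 | latent-scale intraclass correlation (dimensionless) |
| `corr_x1_u0` | 0 | Pearson correlation between x1 and the center effect |
| `n_source_centers` | 100 | centers in the source population |
| `center_size_log_mean`, `center_size_log_sd` | 5.7, 0.3 | lognormal mixing of Poisson center sizes |
| `n_sample_centers`, `n_sample_patients` | 20, 1000 | two-stage sample dimensions |
| `target_incidence` | 0.30 | marginal outcome incidence (0.03 for the low-event setting) |
| `n_reps` | 100 | Monte-Carlo replications |
| `base_seed` | 1 | replication $r$ seeds the RNG at `base_seed + r` |

Design choices where the design was genuinely open:

* **Fixed intercept.** Only the target incidence is specified, so
  `solve_intercept()` finds $\alpha$ with
  $E[\operatorname{logit}^{-1}(\alpha + \sum_m x_m + u_0)] =$ target
  exactly, by Gauss–Hermite quadrature over the normal part of the linear
  predictor (continuous predictors and $u_0$ are jointly normal; the three
  binaries contribute an 8-cell sum) and `uniroot`. This is deterministic
  and seed-free. At ICC 5% and incidence 30% it gives $\alpha = -2.0495$
  and a linear predictor with mean $-1.15$ and sd $1.41$; note that a mean
  of $-1.06$ with the same sd — the other anchor one might adopt — implies
  an incidence of 30.7%, so the two anchors cannot both hold exactly and we
  chose the incidence.
* **Correlated predictor.** With
  $x_1 = \rho\,(\sigma_{x1}/\sigma_{u0})\,u_{0j} + \sqrt{1-\rho^2}\,\sigma_{x1} z$,
  both $\operatorname{corr}(x_1, u_0) = \rho$ and $sd(x_1) = 0.2$ are
  preserved exactly.
* **Patient allocation.** The second sampling stage is simple random
  sampling from the pooled patients of the drawn centers, so larger centers
  contribute proportionally more. Equal per-center allocation would weight
  small centers up and slightly alter the between-cluster SDs.
* **Population regeneration.** Each replication generates its own source
  population (independence across replications); `fixed_population = TRUE`
  reuses one. Apparent-performance aggregates are insensitive to the
  choice, but test-performance measures acquire a shared offset under a
  fixed population: a single population's mean center effect (sd ≈ 0.04
  across draws) shifts every replication's test calibration intercept by
  the same constant, and test c-index percentile ranges collapse to
  model-estimation noise only.

## Estimation details

* The GLMM is fitted by `lme4::glmer` with adaptive Gauss–Hermite
  quadrature, 15 nodes by default; the suite verifies the fitted marginal
  log-likelihood against an independent non-adaptive 101-node quadrature
  evaluation (`glmm_marginal_loglik`, log-sum-exp per cluster) to a
  relative 1e-5, and that 25 nodes move $\hat\sigma^2$ by under 1e-4.
* $\hat u_{0j}$ are posterior modes at the MLE (lme4's conditional modes);
  `eb_u0(type = "mean")` computes posterior means by dense quadrature.
* A variance estimate of 0 is a boundary fit, reported with
  `boundary = TRUE`, not an error; single-cluster input degrades to the
  fixed-effects model with $\sigma^2 = 0$.
* The random-intercept + random-slope recalibration model uses independent
  (diagonal) random effects under the Laplace approximation (adaptive
  quadrature with >1 node is unavailable for vector random effects); the
  diagonal structure keeps the model identifiable at 19–100 clusters.
* Confidence intervals: Wald. For $\sigma^2_{u0}$ the SE is obtained on the
  log-variance scale from a central-difference Hessian of the glmer
  deviance and exponentiated back; no profile-likelihood interval is
  provided.
* **Separation.** A fitted probability within ~1e-7 of 0 or 1 (|linear
  predictor| > 15) flags quasi-separation; the replication is recorded as
  non-converged and excluded from aggregates, with the exclusion count
  reported (`n_nonconverged`, and a scenario is marked `unreliable` above
  20%). Relevant in the 5-center/100-patient and 3%-incidence designs.

## Scope of the simulation evidence

The generator emulates multicenter clinical data with a *normal, additive,
center-level* effect and predictors whose distributions (save optionally
x1) do not vary by center. Real cohorts violate all three in places:
case-mix differs by center, effects can vary by cluster (random slopes),
and cluster size can correlate with outcome. Passing tests therefore
demonstrate correctness of the machinery and the qualitative conclusions —
conditional risks discriminate better overall but only within known
clusters; marginal risks calibrate within clusters where standard-model
risks drift as the ICC grows — not quantitative transportability to any
particular cohort. Non-goals: GEE-style marginal models, penalized or
recalibrated models, non-normal random effects, multiple clustering levels.

## Problem sizes and runtime

The bundled test suite and the acceptance script run each scenario at 50
replications (base scenario ICC 5%, ICC 15%, and the 3%-incidence setting;
20 centers / 1000 patients per replication against 100-center source
populations of ~31,000 patients), which keeps a full pass in the minutes
range on one CPU. The `analysis/03_simulation_tables.R` driver defaults to
100 replications of all nine scenario-grid cells. Monte-Carlo standard
errors of across-replication means scale as $1/\sqrt{reps}$.

## Known limitations

* At ICC 15% the within-cluster calibration spread of fixed-effects risk
  calculations is bounded by the generating $\sigma_{u0} = 0.762$; reported
  reference values exceeding that bound cannot be reached by this (or any)
  implementation of the stated generating process — see the acceptance
  checks for which quantities this affects.
* The diagonal random-effects recalibration model can report a small
  positive random-slope SD on data whose true slope heterogeneity is zero
  (boundary pile-up plus noise in its sampling distribution); medians are
  zero in that case while means are slightly positive.
* Empirical-Bayes modes, not means, enter the conditional risk calculation;
  for very small clusters the two differ, and both shrink toward zero, so
  conditional risks in tiny clusters are close to marginal ones.
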