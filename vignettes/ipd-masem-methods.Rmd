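---
title: "Comparing IPD MASEM estimators by simulation: models, design, and numerical choices"
author: "ipdmasem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing IPD MASEM estimators by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipdmasem)
```

## The problem

Individual participant data (IPD) meta-analysis pools raw per-subject
observations from several primary studies.  When the scientific question is a
*path model* — here the theory of planned behavior, in which attitudes (ATT),
subjective norms (SN), and perceived behavioral control (PBC) predict
intentions (INT), and PBC and INT predict behavior (BEH) — the analyst must
decide how to handle the two-level structure of the data: participants are
nested in studies, and both the covariance structure and the path
coefficients may differ between the participant (within-study) level and the
study-mean (between-study) level.

This package implements, from their matrix-algebraic definitions, the five
estimators commonly considered for this problem, together with a data
generator and a Monte Carlo study runner that evaluates them:

* **NP / CR** — a single-level path model fitted to the pooled sample
  covariance (naive pooling), optionally with cluster-robust (design-based)
  corrections: sandwich standard errors and a mean-scaled chi-square.  Point
  estimates are a mixture of within- and between-level coefficients.
* **PS** — the partially saturated ("maximum") two-level model: the
  hypothesized path structure at the within level, an unstructured
  covariance matrix at the between level.
* **2L** — the structured two-level path model, with path structures at both
  levels.
* **MVMA** — two-stage estimation: the path model is fitted per study, and
  the path coefficients are pooled by fixed-effects multivariate
  meta-analysis (GLS).
* **OSMASEM** — one-stage MASEM: study correlation vectors are pooled by
  inverse-variance GLS and the model-implied correlation structure is fitted
  to the pooled vector, with heterogeneity fixed at zero.

## Models

A path model on $p$ observed variables with coefficient matrix $B$ (strictly
lower triangular under the ordering ATT, SN, PBC, INT, BEH) and residual
covariance $\Psi$ implies

$$\Sigma = (I-B)^{-1}\,\Psi\,(I-B)^{-T}.$$

The two-level model decomposes the total covariance into orthogonal within-
and between-study parts, $\Sigma_T = \Sigma_W + \Sigma_B$, each with its own
$(B, \Psi)$.  The intraclass correlation (ICC) of a variable is the
between-study share of its total variance,
$\sigma_B[v,v] / (\sigma_W[v,v] + \sigma_B[v,v])$.

The five-variable model has 5 free paths, 3 exogenous variances, 3 exogenous
covariances, and 2 residual variances — 13 free parameters against 15
covariance moments, so 2 degrees of freedom.  The partially saturated model
adds 15 free between-level (co)variances and 5 means (df = 2); the
structured two-level model replaces the saturated between level with the
13-parameter structure (df = 4).  The reduced four-variable model used when
behavior is unobserved is saturated (10 parameters, df = 0).

## The data generator

`simulate_meta_dataset()` emulates the generating process of the study
design it reproduces: study means drawn from $N_p(0, \Sigma_B)$, individual
observations drawn around their study mean from $N_p(\mu_j, \Sigma_W)$, and
study sizes drawn uniformly (with replacement) from the integers 90–1238 —
the published range of study sizes in the health-behavior IPD collection the
population values derive from.  Four population scenarios are shipped as
plain-text fixtures and validated against their tabulated covariance values
at load time:

```{r}
sapply(scenario_ids(), function(id) round(icc_profile(get_scenario(id)), 3))
```

* **S1** unequal structures, low ICC (~0.05),
* **S2** unequal structures, medium ICC (0.18–0.40; empirical values),
* **S3** unequal structures, high ICC (0.50),
* **S4** equal structures at both levels (ICC exactly 0.50).

In missing-data conditions, exactly half of the studies (selected uniformly
at random) lose the behavior variable entirely — variable-level, not
participant-level, missingness.  Design choices where the emulated study was
silent, fixed once: grand means are zero (means are nuisance parameters
here); the study-size law is the minimal-assumption uniform over the printed
range; missingness selects exactly $k/2$ studies rather than i.i.d. coin
flips, matching the "50% of studies" description; and child seeds are
spawned counter-style from the master seed per (condition, replication), so
conditions can be run in any order, or in parallel, with identical results.

What the generator deliberately does *not* emulate: non-normal data,
participant-level missingness, unequal within-study models across studies
(within-level parameters are fixed, which is why the meta-analytic
estimators are run as fixed-effects), and empirical quirks of any particular
IPD collection.  Passing tests therefore certify the estimators under the
stated two-level normal process, not under arbitrary real data.

## Estimation

**Single level.**  `fit_path_model_ml()` minimizes the normal-theory
discrepancy
$F(\theta) = \log|\Sigma(\theta)| + \mathrm{tr}(S\Sigma(\theta)^{-1}) -
\log|S| - p$ by BFGS, started at the ordered-regression closed form (which
is the exact ML solution for this recursive model, so the optimizer
essentially verifies stationarity).  The chi-square convention is
$(N-1)\,F$, with sample covariances on the $N-1$ divisor throughout; other
conventions can be rescaled from these.  Standard errors come from the
inverse expected (Fisher) information of the discrepancy.  Convergence
requires an optimizer success and a discrepancy-gradient max-norm below
1e-6.

**Cluster-robust corrections.**  `fit_cluster_robust()` keeps the naive
point estimates and replaces the covariance of the estimates by the cluster
sandwich $A^{-1} (\sum_j g_j g_j')\, A^{-1}$, where $A$ is the expected
information and $g_j$ sums the per-study score contributions at the optimum.
The chi-square is divided by the mean scaling factor
$c = \mathrm{tr}(U\Gamma)/df$, with $U$ the standard residual-weight matrix
of the fit function and $\Gamma$ the cluster-aggregated covariance of the
sample moments; under i.i.d. data with size-one clusters $c \to 1$ and both
corrections collapse to their naive counterparts (tested).  No small-sample
cluster correction is applied.

**Two level.**  `fit_partially_saturated()` and `fit_twolevel()` use direct
full-information maximum likelihood on unbalanced clusters, evaluated from
per-cluster sufficient statistics: within-cluster deviations contribute
$n_j - 1$ degrees of freedom on $\Sigma_W$, and each cluster mean is one
observation with covariance $\Sigma_B + \Sigma_W/n_j$ (plus the
$p\log n_j$ Jacobian term from the orthonormal decomposition).  Writing
$\Sigma_W = LL'$ and eigendecomposing $L^{-1}\Sigma_B L^{-T}$ puts all
cluster-mean covariances in a common basis, so each likelihood evaluation is
a cheap $O(k)$ pass; the evaluation is compiled (RcppArmadillo), as is usual
for this class of likelihood.  Studies missing the behavior variable
contribute the corresponding 4-variable marginal.  Grand means are profiled
out by GLS inside every evaluation (they remain counted among the model's
parameters).  Both level covariances are parameterized by log-Cholesky
factors (exogenous block plus log residual variances for structured levels),
which keeps them positive definite by construction — one uniform
parameterization instead of a barrier.  Chi-squares are likelihood ratios
against the saturated-saturated baseline.

Convergence of the two-level optimizer: BFGS with forward-difference
gradients (step $10^{-6}(1+|\theta_i|)$), a central-difference polishing
restart if the gradient max-norm exceeds 0.5, and a final criterion of
max-norm below 1 on the $-2\log L$ scale.  At the sample sizes of this
design ($-2\log L \sim 4\times10^5$, curvature $\sim 10^4$), a gradient norm
of 1 perturbs the likelihood-ratio chi-square by roughly $10^{-4}$ —
far below anything that affects estimates or rejection rates — while
gradient tolerances appropriate for unit-scale objectives would misreport
finite-difference noise as non-convergence.

**Meta-analytic.**  Stage one of `fit_mvma()` fits the per-study models by
ML (the reduced three-path model in behavior-masked studies), with sampling
covariances from the expected-information inverse; stage two is fixed-effects
GLS pooling with selection matrices accommodating studies that contribute 3
of the 5 effects.  `fit_osmasem()` computes study correlation vectors
(strict half-vectorization, column-major over the lower triangle — one fixed
ordering project-wide) with normal-theory (Olkin–Siotani) sampling
covariances, pools them by GLS, and minimizes the GLS discrepancy of the
standardized model-implied correlation structure; residual variances are
solved analytically to keep implied variances at one, and infeasibility of
that constraint is reported as non-convergence.  The discrepancy is
minimized with a fixed weight matrix (two-step GLS) rather than iteratively
reweighted ML: deterministic, fast, and consistent with the fixed-effects
framing; its minimized value is the chi-square.  Both estimators are run as
fixed-effects ($T^2 = 0$) because the generator holds within-level
parameters fixed across studies.

## Evaluation

`run_condition()` fits every requested method to the *same* generated
collection per replication (paired comparison), records failures as
non-converged replications, and `summarize_replications()` computes, over
converged replications only: convergence rates, mean estimates, RMSE
$\sqrt{\tfrac1{n}\sum_i(\hat\beta_i-\beta)^2}$, percentage relative SE bias
$100(\overline{SE} - \sigma_\beta)/\sigma_\beta$ (|bias| ≤ 10% acceptable),
and exact-fit (chi-square $p < \alpha$) and close-fit rejection rates.
Close fit is the null RMSEA < .05, tested against the noncentral chi-square
with noncentrality $0.05^2\,df\,(N-1)$ and rejected when its p-value falls
below $\alpha = .05$ (the conventional direction).  RMSEA for the two-level
models uses the total participant count as $N$ — a documented knob, since
other choices (cluster count) exist.  Methods falling below 50% convergence
in a condition are flagged and their cells left empty in `report()` tables.

## Problem sizes and reproducibility

The full design is 4 scenarios × k ∈ {10, 30, 50} × 2 missingness patterns
with 1000 replications per condition; at those settings the grid is an
overnight single-CPU run.  The package's tests and the acceptance script
run the informative slices at reduced scale, chosen to keep Monte Carlo
error well inside the margins being tested: 200 replications for
parameter-recovery and close-fit summaries, 300 for the naive-pooling
standard-error and exact-fit pathologies, and a reduced grid (k ∈ {30, 50})
for the close-fit sweep.  Every run derives its per-replication seeds from a
single master seed, so results are bit-reproducible and order-independent.

A note on the criterion "mean estimate within 2 Monte Carlo standard errors
of the population value": that check has, by construction, roughly a 5%
false-alarm probability per path under resampling, and at very large
replication counts it resolves finite-sample biases of order $10^{-4}$ that
are scientifically irrelevant here.  It is applied at the design's stated
scale (200 replications, k = 50), where the Monte Carlo margin comfortably
dominates such bias.

## Known limitations

* Estimation is tailored to recursive path models with a saturated
  exogenous block; latent variables, mean structures (beyond the free
  two-level means), and non-recursive systems are out of scope.
* The cluster-robust scaled statistic implements mean (Satorra–Bentler
  type) scaling; software packages differ in the exact scaling variant and
  in small-sample corrections, so digit-level agreement with any particular
  implementation is not a goal — the qualitative bias patterns are.
* Random-effects MVMA/OSMASEM (free $T^2$) are not implemented.
* Convergence rates of two-level fits at k = 10 with missing data depend
  heavily on the optimizer and parameterization; they are reported honestly
  but are not comparable digit-for-digit across software.
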