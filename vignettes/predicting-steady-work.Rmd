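---
title: "Predicting steady work from functional vs medical improvement: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting steady work from functional vs medical improvement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steadywork)
```

## The scientific question

For people with mental health conditions who were recently denied disability
benefits, does *functional* improvement — self-reported work-related ability
as measured by the eight WD-FAB scales — predict a return to steady work
better than *medical* improvement (symptom scores such as the Colorado
Symptom Index, substance screeners, BMI, and health-care utilization
counts)? The package implements the full comparison pipeline: a calibrated
synthetic cohort emulating the Supported Employment Demonstration public
use file (SED-PUF), standardized baseline/change design matrices under four
nested predictor sets, a sparse hierarchical Bayesian logistic regression
with in-model handling of missing predictors, two nonlinear Bayesian
comparators, and leave-one-out cross-validated ROC / precision-recall
adjudication.

Everything runs on synthetic data: the real SED-PUF is distributed by the
US Social Security Administration and is deliberately neither bundled nor
downloaded. Users who obtain it can slot a matching CSV into
`run_config(generator = "<cohort.csv>")`.

## The outcome model

For participant $i$ in follow-up year $w \in \{1,2,3\}$, steady work
(employment at half time or more) is modeled as

$$y_{iw} \sim \mathrm{Bernoulli}\left(\sigma(\alpha + \delta_w +
  x_{iw}^\top \beta + u_i)\right),$$

where $x_{iw}$ stacks standardized baseline values and standardized
changes-from-baseline of every predictor in the active set, plus unscaled
indicator columns, $\delta_w$ are year dummies, and
$u_i \sim \mathcal N(0, \sigma_u^2)$ is a participant-level random
intercept accounting for the repeated annual outcomes. Because every
continuous predictor is standardized (baselines by their mean/SD, changes
by the mean difference and SD of differences, both over observed analysis
rows), coefficient magnitudes are directly comparable, and predictors are
ranked by $|\mathbb E[\log \mathrm{OR}]|$.

**Sparsity.** Slopes carry a regularized horseshoe prior:
$\beta_j = c\,t_j z_j / \sqrt{c^2 + t_j^2}$ with $z_j \sim \mathcal N(0,1)$,
$t_j = \tau \lambda_j$, local scales $\lambda_j \sim C^+(0,1)$, global
scale $\tau \sim C^+(0, \tau_0)$ with $\tau_0 = 1$, and slab width $c = 2$.
Small effects are shrunk aggressively toward zero while genuinely large
effects escape to the (finite) slab — which is what makes the magnitude
ranking meaningful. Wave dummies and the intercept get Normal(0, 2) priors
and are never penalized.

**Missing predictors.** Function scores are missing in whole-wave blocks
(0, 7, 14, or 21 of the seven modelled scales), and the Community Mobility
scales are missing informatively — they are only administered to people who
drive, ride public transit, or use a wheelchair. The model therefore (i)
replaces Community Mobility scores by presence indicators, and (ii) treats
every remaining missing standardized cell as a latent parameter with a
per-column Gaussian model ($x^{mis}_{k} \sim \mathcal N(\mu_j, s_j)$ with
weakly-informative hyperpriors), sampled jointly with the coefficients.
This realizes missing-value imputation *inside* the model: the likelihood
is averaged over plausible values rather than conditioned on a single
imputation. `marginalized_log_likelihood()` provides the independent
quadrature/enumeration route used to validate this scheme exactly on small
cases.

## Inference

The default engine is mean-field Gaussian variational inference with
reparameterization gradients, analytic entropy, and Adam updates
(`1/sqrt(t)` decay, learning rate 0.02, 2 Monte Carlo samples per step,
2000 steps by default, 1000 posterior draws). It is deterministic given a
seed, and fast enough to fit the full 12-cell model grid on a laptop-scale
budget. Two caveats are documented rather than hidden: mean-field
approximations underestimate posterior correlations, and the ELBO
convergence flag (`diagnostics$converged`) is conservative.

A Markov chain Monte Carlo path (`method = "mcmc"`) exists for
validation-scale problems — normal priors, no hierarchy, no missing cells —
implemented as adaptive random-walk Metropolis with covariance adaptation
frozen after warmup. We chose this sampler over a gradient-based one
because its only job is to provide well-calibrated posterior draws on
problems with a handful of parameters (exact-refit LOO checks at
$n \approx 30$), where random-walk mixing is entirely adequate and the
implementation surface is small.

For the Bayesian neural network, the variational means are initialized with
seeded Gaussian noise: a zero start sits exactly on the hidden-unit
permutation-symmetry saddle and reliably stalls there.

## The comparator models

*Piecewise Bayesian GLM.* `define_partition()` cuts chosen design columns
at empirical quantiles (default: a mental-function baseline composite and
baseline age, two bins each; regions under 10 observations merge into a
neighbor) and `fit_piecewise()` fits
$\eta = \alpha + a_r + x^\top(\beta + \delta_r)$ with
$\delta_r \sim \mathcal N(0, s_{off})$, $s_{off} = 0.5$, shrinking each
local region toward the global model. With one region the offsets are
dropped entirely, so the model *is* the global GLM; as $s_{off} \to 0$ it
collapses to it. The exact local-region construction of the original
additive method is not fully specified in the source text; the quantile
tensor product with hierarchical shrinkage is this package's concrete
choice, and the partition is configurable.

*Bayesian neural network.* One tanh hidden layer of width 12, standard
normal priors on all weights, logistic output. Missing inputs use
zero-fill-after-standardization plus missing-indicator columns — a
pragmatic divergence from the linear model's latent scheme, chosen because
latent inputs interact with every hidden unit and would dominate the
parameter count.

## Model adjudication

`psis_loo()` computes each observation's leave-one-out predictive
probability from a single fit by importance weighting with
Pareto-smoothed importance sampling: ratios $1/p(y_i\mid\theta_s)$, the
largest `min(0.2 S, 3 sqrt(S))` of them replaced by expected order
statistics of a fitted generalized Pareto tail, truncated at the raw
maximum. The per-observation shape diagnostic $k$ flags unreliable weights
at the conventional 0.7 cutoff, and an exact-refit fallback can re-fit the
model with the observation held out. ROC curves use a threshold sweep with
tied scores grouped and trapezoidal area (equal to the Mann-Whitney
statistic with ties counted one half); precision-recall areas use the
average-precision step convention, which avoids the optimistic linear
interpolation of trapezoids in PR space. Curves pool all participant-years,
matching one-observation-at-a-time LOO; leaving out whole participants
instead is a flagged alternative we did not implement as the default.

One behavior worth knowing about: pointwise LOO probabilities of a model
with *no* predictive signal are not exchangeable noise — removing a
positive observation pulls its prediction slightly down, removing a
negative one pulls it up — so LOO AUROC of a null model sits *below* 0.5,
dramatically so when fitted probabilities are nearly constant. This is a
property of LOO scores, not a defect of the curves; comparisons between
models remain valid because all models are scored the same way.

## The synthetic cohort generator

The generator emulates the published wave-level statistics of the SED
cohort (2,944 participants, 4 annual waves):

* **Functional scales.** Gaussian baselines with the published means/SDs;
  changes-from-baseline Gaussian with wave-specific published moments. A
  baseline-change correlation of $-0.35$ (regression to the mean)
  reproduces the published wave-level score dispersions — e.g. for Mood &
  Emotions, $(14.3^2 - 12^2 - 12.9^2)/(2 \cdot 12 \cdot 12.9) = -0.34$.
  Cross-scale correlation is exchangeable by domain (0.4 within mental and
  within physical, 0.2 across; configurable) — the source tables publish no
  correlation structure, so these are stand-ins.
* **Medical variables.** Wave-level published means/SDs. Continuous scores
  (CSI, BMI) are floor-truncated Gaussians whose locations are
  moment-matched by root finding so truncation does not bias the published
  means; waves are coupled through a shared standardized baseline residual
  with per-variable correlations back-solved from the published change SDs.
  Counts (DAST, AUDIT, ER visits, inpatient admissions) are
  negative-binomial marginals — the published SDs exceed the means, so
  overdispersion is required — linked across waves by a Gaussian copula.
  Count change SDs are therefore approximate; count means are exact.
* **Missingness.** Block patterns over {0, 7, 14, 21} missing function
  measurements blank whole follow-up waves of the seven modelled scales
  (default probabilities 0.55/0.20/0.15/0.10, chosen to match the observed
  qualitative clustering; configurable, not a published value). Community
  Mobility presence flags are Bernoulli per wave with the published
  Has-score rates; the implied ~60% missing Drive scores match the
  published figure. Community Mobility *scores* are never generated — no
  moments are published and the analysis uses only presence.
* **Outcome.** Drawn per follow-up year from the logistic model above with
  a random intercept SD of 0.5 (the source does not state the serial
  dependence; this induces realistic within-person persistence and is
  configurable). Wave intercepts in the bundled default configuration are
  calibrated at config-build time — an internal fixed-seed covariate draw
  of 30,000 participants and a root solve per wave — so realized
  prevalences match the published 0.155/0.192/0.173 regardless of the
  chosen slopes.

What passing tests on this generator do **not** show: the synthetic cohort
has Gaussian scales, exchangeable correlations, missingness independent of
the latent scores given the block pattern, and a correctly specified
outcome model. Real SED data have none of these guarantees, so test
results certify the *machinery*, not the substantive findings on real data.

## Problem sizes and numerical choices

The test suite exercises deliberately scaled problems, chosen as the
smallest sizes at which each property is sharply testable: calibration
checks at the published
cohort size (n = 2944, seconds); parameter recovery over 20 replicates at
n = 2000 with 20 predictors (3 nonzero); exact-refit LOO comparisons at
n = 30 with 8000 MCMC draws; the functional-vs-medical headline on a 600
participant cohort across all three model families; and the missingness
sensitivity grid (m_max 0/7/14) at 1000 participants. Variance of sample
SDs of heavily overdispersed counts is acknowledged with a delta-method
Monte Carlo allowance on top of the 10% calibration band.

Degenerate inputs are defined rather than left to chance: zero change SDs
produce noise-free follow-ups (and contribute zero to the standardized
linear predictor); all-tied prediction scores yield the single PR point
(recall 1, precision = prevalence); empty regions vanish from partitions
and undersized ones merge into a neighbor; a zero-variance continuous
column is an explicit error naming the column; a statistic with no
observed values is reported as `NA`, never zero.

## Known limitations

* Mean-field VI underestimates uncertainty; credible-interval coverage is
  verified empirically in the tests but will degrade with highly
  correlated designs.
* The per-column Gaussian missing-value model ignores cross-column
  correlation; with strongly correlated predictors and heavy missingness
  it attenuates coefficients (demonstrated in the test suite with
  independent predictors as the correctly-specified contrast).
* Changes are standardized pooled across waves (matching a single mean
  difference per variable); per-wave standardization is a constructor
  argument away but not the default.
* The piecewise model's partition is a modeling choice, not an estimate;
  results should be read conditional on it.
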