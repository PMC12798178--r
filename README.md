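# steadywork

Does improvement in self-reported *work-related function* predict a return
to steady employment better than improvement in *medical* measures? This
package implements, as a tested and fully synthetic-data-driven pipeline,
that comparison for longitudinal cohorts patterned on the Supported
Employment Demonstration public use file (SED-PUF): recently denied
disability applicants with mental health conditions, followed over a
baseline and three annual waves, with the eight WD-FAB functional scales,
medical assessments (CSI, BMI, DAST, AUDIT, ER/inpatient/outpatient
utilization), demographics, and a binary *steady work* outcome per
follow-up year.

It is intended for methodologists and health-outcomes researchers who want
to exercise, extend, or audit the analysis before (or instead of) obtaining
the restricted SED-PUF. The real data are never bundled or downloaded; a
matching CSV can be slotted in via `run_config(generator = "cohort.csv")`.

## The model at its core

Steady work for participant *i* in year *w* follows a Bernoulli-logit
model

> y<sub>iw</sub> ~ Bernoulli( sigma( alpha + delta<sub>w</sub> +
> x<sub>iw</sub><sup>T</sup> beta + u<sub>i</sub> ) )

where x<sub>iw</sub> contains the **standardized baseline** and the
**standardized change-from-baseline** of every predictor in the active set
(plus presence indicators for the informatively missing Community Mobility
scales), u<sub>i</sub> is a participant random intercept, and the slopes
beta carry a **regularized horseshoe** prior (local scales C+(0,1), global
scale C+(0,1), slab width 2) so that impactful predictors can be read off
by posterior |log OR| magnitude. Missing predictor cells are latent
parameters with per-column Gaussian models, sampled jointly with the
coefficients — imputation happens inside the model by averaging over
plausible values. Inference is seeded mean-field variational (Adam,
reparameterization gradients), with an adaptive-Metropolis MCMC path for
validation-scale problems.

Four nested predictor sets (`demographic`, `demographic+function`,
`demographic+medical`, `full`) and three model families (the sparse linear
model, a piecewise Bayesian GLM over quantile regions, and a Bayesian
neural network with a 12-unit tanh hidden layer) are adjudicated by
**PSIS-LOO** cross-validated ROC and precision-recall curves.

## Worked example

```r
library(steadywork)

cfg <- default_generator_config(n_participants = 800, seed = 7)
cohort <- generate_cohort(cfg)
cohort
#> <sw_cohort> 800 participants x 4 waves
#>   steady-work rate (years 1-3): 0.159
#>   missing follow-up function cells: 27%

design <- build_design(cohort, set = "demographic+function", m_max = 14)
fit <- fit_sparse_logistic(design, seed = 7)
head(summarize_odds_ratios(fit), 4)
#>                      predictor  or_mean   or_low  or_high log_or_mean rank
#> 1                        wave2 1.421779 1.173625 1.699952   0.3472849    1
#> 2              comm_cog_change 1.394963 1.194681 1.735192   0.3280518    2
#> 3 work_history:worked_past_2yr 1.363402 1.111996 1.869036   0.3007876    3
#> 4                        wave3 1.345549 1.113522 1.633822   0.2916441    4

loo <- psis_loo(fit)
roc_curve(loo)
#> <sw_curve> ROC: area = 0.6086 (2140 points)
```

The odds ratios are per SD of the standardized predictor: a one-SD
year-over-year improvement in Communication & Cognition multiplies the
annual odds of steady work by about 1.39 in this synthetic cohort, and the
top-ranked predictors mirror the generating coefficients (functional
changes, work history) alongside the year terms. The LOO AUROC of 0.61 is
the cross-validated discrimination of this single submodel.

The whole grid — predictor sets x model families, with comparison tables,
odds-ratio CSVs, curve coordinates and a provenance-hashed JSON report —
runs through:

```r
report <- run_pipeline(run_config(generator = cfg, seed = 7), out_dir = "out")
report$comparison
```

or from a shell via the thin wrapper
`inst/scripts/steadywork-pipeline.R` (`--config`, `--cohort`, `--seed`,
`--m-max`, `--sets`, `--families`, `--sensitivity`).

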