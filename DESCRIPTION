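Package: steadywork
Title: Bayesian Prediction of Steady Work from Functional and Medical
    Improvement in Longitudinal Disability Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whether improvement in self-reported
    work-related function predicts steady employment better than medical
    and health-care-utilization measures, in longitudinal cohorts
    patterned on the Supported Employment Demonstration public use file.
    Provides a seeded synthetic cohort generator calibrated to published
    wave-level summary statistics (WD-FAB functional scales, medical
    assessments, informative Community Mobility missingness), standardized
    baseline/change design matrices with the four nested predictor sets,
    sparse hierarchical Bayesian logistic regression with in-model
    marginalization over missing covariates (regularized horseshoe prior,
    mean-field variational inference, validation-scale MCMC), piecewise
    Bayesian GLM and Bayesian neural network comparators, and
    Pareto-smoothed importance-sampling leave-one-out (PSIS-LOO)
    cross-validated ROC and precision-recall model adjudication.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
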