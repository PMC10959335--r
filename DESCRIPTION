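Package: fmacausal
Title: Frequentist Model Averaging for Causal Effects in New-User Claims Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates average treatment effects on time-to-event and binary
    outcomes in new-user cohorts derived from administrative-claims-style data
    by frequentist model averaging (FMA) over an ensemble of analysis
    strategies (propensity-score weighting, matching and stratification,
    and direct outcome regression), scored by cross-validated mean squared
    prediction error on restricted-mean-survival-time or restricted-hazard
    pseudo-observations, with percentile-bootstrap confidence intervals.
    Includes a seeded synthetic claims generator with known counterfactual
    truths, a cohort builder implementing index assignment, adherence (PDC),
    continuous-enrolment, diagnosis and prevalent-disease attrition rules
    with a full audit trail, and covariate-balance diagnostics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival,
    glmnet,
    ranger,
    xgboost,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
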