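Package: subcortgrowth
Title: Hierarchical Growth Modeling of Early-Childhood Subcortical Brain
    Volumes and Cognition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for mapping brain development from birth through early
    childhood in multicohort longitudinal studies. Fits hierarchical
    asymptotic (Gompertz-rate) nonlinear mixed growth models to regional
    brain volumes with subject-specific intercepts and asymptotes, cohort
    mean shifts and cohort-specific residual variances; derives maturation
    ages (age at 99% of asymptotic volume); fits heteroscedastic linear
    mixed models for ICV-scaled volumes and Mullen cognitive raw scores;
    correlates subject-level predicted volumes and cognitive scores at age
    2 with bootstrap comparison of correlations between full-term and
    preterm strata; runs product-of-coefficients mediation with bootstrap
    confidence intervals; and assesses robustness by repeated split-sample
    replication. Includes a synthetic multicohort generator emulating the
    statistical structure of such studies so the full pipeline is testable
    without restricted data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme,
    lme4,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
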