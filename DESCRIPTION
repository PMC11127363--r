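Package: phrflow
Title: Conditional Normalizing Flows for Anomaly Detection in Personal
    Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semi-supervised detection of chronic-disease cases in tabular
    personal-health-record (PHR) cohorts under extreme class imbalance. The
    core model is a conditional normalizing flow built from a conditional
    affine transformation and volume-preserving GIN coupling blocks, trained
    by exact maximum likelihood on unaffected participants only and scored by
    the base-density of the latent representation. The package also provides
    a synthetic PHR cohort generator, a leakage-guarded preprocessing chain
    (log transform, chained-regression imputation, robust scaling, group-wise
    PCA), a base-rate-preserving evaluation protocol with repeated-split
    confidence intervals and positive-undersampling sweeps, and classical
    supervised and one-class baselines with resampling wrappers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    mclust,
    ranger,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
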