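Package: agestack
Title: Multi-View Stacking Ensemble Aging Clocks for Gut Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds microbiome aging clocks from compositional metagenomic
    profiles. Provides confounder-aware cohort screening (covariate-adjusted
    PERMANOVA and iterative decoupling of geography from age), compositional
    preprocessing (multiplicative zero replacement and the centered log-ratio
    transform), a registry of heterogeneous base regressors with a repeated
    cross-validation harness, feature selection with a degradation-count
    adjudication rule, two-stage stacking with out-of-fold predictions and
    multi-view late fusion, and permutation-feature-importance biomarker
    discovery with Spearman age-association annotation. Includes a synthetic
    two-view cohort generator with planted age signals and controllable
    geographic confounding so the full pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    glmnet,
    e1071,
    ranger,
    rpart,
    xgboost,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
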