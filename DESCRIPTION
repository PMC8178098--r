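Package: phasesom
Title: Two-Stage Self-Organizing-Map Biomarker Discovery for Phase-Resolved Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a biomarker-discovery workflow for time-series
    (three-phase) gene expression cohorts: data curation (zero imputation,
    consensus multivariate outlier detection, high-covariance gene
    filtering), cross-platform quantile-normalization meta-analysis with
    median probe-to-gene collapse, two-stage patient clustering by
    hand-rolled rectangular self-organizing maps (one map per clinical
    phase, a second map over the per-phase cluster labels), hierarchical
    super-cluster formation, per-phase one-way ANOVA feature selection
    under Benjamini-Hochberg false-discovery-rate control with cross-phase
    intersection, and a boosting-classifier comparison (AdaBoost and
    regularized gradient-boosted trees) of the selected genes against a
    reference gene set under repeated stratified cross-validation. A
    synthetic-cohort generator with planted super-cluster structure and
    phase-consistent marker genes makes the entire pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    limma,
    Rcpp,
    stats,
    tools,
    utils,
    xgboost,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
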