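Package: oncosepsis
Title: Sepsis Risk Analysis for Cancer Cohorts from Longitudinal Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for analysing sepsis risk in patients with
    cancer from longitudinal electronic health records. Provides a synthetic
    cohort generator with configurable group-level demographics, lab-value
    distributions and co-prescription structure; Sepsis-3 onset labelling from
    SOFA organ-failure scores and suspected-infection windows; observation-window
    filtering, robust outlier removal and stratified mean imputation; FP-growth
    mining of same-day co-prescription baskets with support-thresholded
    selection and graph-topology ranking; drug-pair relationship vectorization
    (interaction, harmonized average, arctangent); Welch t-test screening of lab
    panels with significance tiers; and stratified cross-validated evaluation of
    classifier families over nested feature sets with path-dependent Tree SHAP
    feature-contribution ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    nnet,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
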