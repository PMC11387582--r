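Package: smaproteo
Title: CSF Proteomics Biomarker Discovery Workflows for Spinal Muscular
    Atrophy Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for biomarker discovery in paired-timepoint
    cerebrospinal-fluid (CSF) proteomics cohorts of spinal muscular atrophy
    (SMA) patients. Implements a repeated stratified-split Random-Forest
    consensus feature selector (Gini-importance top-k intersection) for
    baseline severity stratification, leakage-aware preprocessing
    (log2/median-centering, completeness filtering, train-only scaling),
    single-factor PERMANOVA with exact or sampled permutations, age-adjusted
    per-protein ANCOVA screening, paired and responder differential-abundance
    contrasts with Benjamini-Hochberg correction, Ward-D2 clustering of
    significant proteins with a two-cluster up/down cut, hypergeometric
    over-representation analysis against GMT gene sets, and a synthetic
    cohort generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
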