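Package: cslv
Title: Chromosomal-Scale Length Variation Risk Scores from SNP-Array Log R Ratios
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes chromosomal-scale length variation (CSLV) features --
    mean log R ratio (LRR) over equal-length chromosome segments -- from SNP
    genotyping array intensity data, and builds germline cancer risk scores
    on top of them. Provides readers for marker manifests and LRR matrices
    (wide and Illumina final-report-style long dialects), age-matched
    case:control undersampling, stratified train/test splitting, a small
    cross-validated model zoo (gradient boosting, random forest, logistic
    regression and a stacked ensemble), Mann-Whitney AUC with bootstrap
    confidence intervals, score-quintile risk stratification with odds
    ratios, cross-population transfer evaluation, permutation feature
    importance, and a synthetic LRR cohort simulator with known copy-number
    ground truth for end-to-end testing without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
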