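Package: prsbench
Title: Ancestry-Aware Construction and Benchmarking of Polygenic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and compares polygenic risk score (PRS) models for binary
    disease traits across genetically diverse cohorts. Implements a fixed-panel
    score weighted by interchangeable ancestry-specific GWAS summary statistics,
    a clumping-and-thresholding score with best-fit p-value threshold selection
    on Nagelkerke pseudo-R2 (liability-scale adjusted for case-control
    ascertainment), summary-statistics harmonization and fixed-effects
    meta-analysis, a common evaluation suite (AUC with DeLong comparisons,
    odds ratio per score standard deviation, ROC operating-point metrics),
    Dudbridge-style power and minimum-sample-size calculations, and a
    liability-threshold simulator of multi-ancestry case-control cohorts with
    Balding-Nichols allele-frequency divergence, blockwise linkage
    disequilibrium, and admixture.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    metafor
Config/testthat/edition: 3
RoxygenNote: 7.3.3
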