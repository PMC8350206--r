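Package: metamethyl
Title: EWAS Meta-Analysis of Age in Skeletal Muscle Methylomes and a Muscle Epigenetic Clock
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for epigenome-wide association study (EWAS)
    meta-analysis of age across heterogeneous DNA methylation cohorts:
    per-cohort covariate-adjusted linear models with empirical-Bayes variance
    moderation and repeated-measures handling, empirical-null bias and
    inflation correction of test statistics, fixed-effects inverse-variance
    meta-analysis with Cochran's Q heterogeneity, kernel-smoothed
    differentially methylated region (DMR) calling, genomic-context and
    CpG-bias-corrected gene-set enrichment, multi-omic overlap testing, and a
    muscle epigenetic clock (beta-mixture quantile calibration, transformed-age
    elastic net, leave-one-dataset-out evaluation). Ships a multi-cohort
    synthetic methylome generator so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    data.table,
    limma,
    glmnet,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    statmod
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
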