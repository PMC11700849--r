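Package: pgstrat
Title: Polygenic Score Construction and Lifestyle-Stratified Obesity Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds polygenic scores (PGS) for obesity from GWAS summary
    statistics by LD clumping plus p-value thresholding (P+T) and by
    point-normal Bayesian shrinkage with Gibbs sampling over LD windows
    (LDpred-style), selects models by covariate-adjusted AUC, stratifies
    individuals into percentile-based genetic risk categories, estimates
    lifestyle quintile trend odds ratios within risk strata, pools cohorts
    by fixed/random-effects meta-analysis, and runs simulation-based power
    calculations for multi-cohort designs. Includes a calibrated synthetic
    multi-cohort generator (LD-blocked dosages, point-normal causal
    effects, BMI liability model with lifestyle covariates) so the full
    pipeline is testable without access to restricted cohort data, plus
    quality-control filters with an exact Hardy-Weinberg test and readers
    and writers for PGS Catalog scoring files and dosage matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pROC,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    jsonlite,
    vcfR,
    optparse
Config/testthat/edition: 3
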