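Package: methylNurture
Title: Direct and Indirect Polygenic Effects on Offspring DNA Methylation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Separates direct genetic effects from genetic nurture (indirect
    parental genetic effects) on the offspring methylome. Implements per-CpG
    generalized estimating equation (GEE) regression of residualized
    methylation beta-values on offspring, maternal, and paternal polygenic
    scores for multiple traits, with cluster-robust (sandwich) standard
    errors by family; methylation preprocessing (QC-flag filtering, IQR
    outlier masking, missingness-aware imputation, covariate
    residualization, top-variance probe selection); polygenic-score
    preparation (residualization on genetic principal components and
    platform dummies, standardization, zero-imputation of missing parental
    scores); the effective number of independent tests by matrix spectral
    decomposition with the resulting Bonferroni threshold; hit
    classification by predictor role and trait; and a synthetic
    nuclear-twin-family generator (Mendelian genotype transmission,
    polygenic scores, covariates, methylation with known direct and
    indirect effects) so the full pipeline runs with ground truth and no
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    sandwich,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
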