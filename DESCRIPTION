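Package: omicpred
Title: Phenotype Prediction from SNP Genotypes and Gene Expression by
    Bayesian Whole-Genome Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-genome regression of quantitative phenotypes on
    genome-wide SNP genotypes and/or transcriptome-wide gene expression
    levels, with Gaussian (Bayesian ridge) or double-exponential (Bayesian
    lasso) coefficient priors fitted by Gibbs sampling.  Provides block-wise
    partitioning of phenotypic variance from the posterior samples, deviance
    information criterion (DIC) model comparison, gene-selection filters
    (among-family ANOVA significance, tissue specificity against a
    multi-organ reference atlas, raw-scale standard deviation),
    family-grouped k-fold cross-validation of prediction accuracy with
    paired t-tests between model configurations, genotype and expression
    quality control, and a synthetic-data generator emulating the full-sib
    family structure of heterogeneous-stock mouse data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
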