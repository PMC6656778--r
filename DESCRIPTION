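Package: twmr
Title: Transcriptome-Wide Mendelian Randomization from GWAS and eQTL Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Multi-instrument, multi-exposure (multi-gene) Mendelian
    randomization for estimating causal effects of gene expression on
    complex traits from GWAS and cis-eQTL summary statistics with
    reference-panel linkage disequilibrium. Implements the inverse-variance
    weighted estimator for correlated instruments, delta-method standard
    errors, an iterative Cochran-Q heterogeneity filter for pleiotropic
    instruments, stepwise conditional selection of independent eQTL
    instruments, co-regulated gene filtering, a genotype-level simulation
    study comparing the multi-gene and single-gene estimators, and
    downstream utilities (enrichment odds ratios, trait-trait expression
    correlation, novel-locus classification).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
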