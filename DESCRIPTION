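Package: ricepanel
Title: Design, Quality Control and Genomic Prediction for Rice Amplicon SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the full computational workflow around a ~1000-SNP rice
    amplicon genotyping panel: panel design from candidate SNP resources
    (call-rate/MAF filters and physical gap filling), HapMap genotype I/O,
    per-marker quality control, replicate repeatability and cross-platform
    concordance, LD-kNN genotype imputation, trait-marker diagnostics
    (utility, false positive and false negative rates), predicted-F1
    validation, population structure (PCA, Ward clustering, silhouette),
    pairwise polymorphism, and genomic selection (ridge/GBLUP, Bayesian
    whole-genome regression, two-kernel RKHS, pedigree BLUP) with
    family-stratified cross-validation. Includes generators for synthetic
    indica/japonica breeding germplasm so every stage can be exercised
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    lme4,
    cluster,
    ape,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
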