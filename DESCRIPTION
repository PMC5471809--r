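Package: fattygs
Title: Genomic Evaluation of Fatty-Acid Composition in Beef Cattle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested pipeline for genomic evaluation of fatty-acid traits in
    beef cattle: construction of fatty-acid group traits and fixed-effect
    adjusted phenotypes, PLINK bed/bim/fam input with quality-control filters,
    the VanRaden genomic relationship matrix, REML estimation of heritability
    and genetic correlations, a BayesB Markov chain Monte Carlo sampler with
    100 kb window-based partitioning of genetic variance, GRAMMAR-GC
    single-SNP association scans with genomic control, region-based kernel
    score tests, linkage-disequilibrium r-squared, and cross-validated
    genomic prediction by GBLUP and BayesB. Includes a synthetic-data
    generator producing LD-structured genotypes and phenotypes with known
    genetic architecture so every stage can be checked against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
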