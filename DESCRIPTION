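Package: regionwas
Title: Multi-Stage Region-Based Discovery for Case-Control GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A four-stage region-based discovery pipeline for case-control
    genome-wide association studies: a sliding-window Bayesian decision-tree
    screen producing posterior log-odds (PLO) scores with permutation nulls,
    covariate-adjusted generalized Berk-Jones (GBJ) region tests on
    individual-level genotypes or on summary statistics with reference
    linkage disequilibrium, sample-size-weighted Z meta-analysis with
    sex-difference testing, and the supporting quality-control, relatedness
    and population-structure machinery. Includes a multi-study case-control
    genotype simulator with haplotype-block linkage disequilibrium for
    calibration and power studies, and readers/writers for PLINK binary
    genotypes, BED region lists and per-SNP summary-statistic tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
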