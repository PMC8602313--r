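Package: mdavar
Title: Single-Cell SNV Calling and Genotyping for MDA-Amplified Cells with a
    Bulk Background Sample
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Probabilistic calling and genotyping of single nucleotide
    variants in diploid single cells whose DNA was whole-genome amplified by
    multiple displacement amplification (MDA), evaluated jointly with an
    unamplified bulk sample from the same cell population. Amplification bias
    up to complete allele dropout is modelled with coverage-dependent
    beta-binomial read-count distributions; the joint cell/bulk likelihood is
    partitioned into seven mutually exclusive single-cell events whose
    posterior probabilities support genotyping, bulk-driven imputation of
    zero-coverage sites, Bayesian false discovery rate control over compound
    events, and allele-dropout-rate estimation. Includes a generative
    simulator for calibration studies, pileup extraction from alignment
    files, and VCF output with PHRED-scaled event probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    GenomicRanges,
    IRanges,
    jsonlite,
    optparse,
    purrr,
    Rsamtools,
    testthat (>= 3.0.0),
    vcfR,
    withr,
    yaml
Config/testthat/edition: 3
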