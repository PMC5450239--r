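Package: hlafreq
Title: HLA Haplotype Frequency Estimation from Ambiguous and Heterogeneous
    Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates multi-locus HLA haplotype frequencies from unphased
    population genotype records with an expectation-maximization algorithm
    under Hardy-Weinberg equilibrium. Includes a complete preprocessing layer
    that parses and validates WHO nomenclature allele designations, expands
    NMDP multiple allele codes and genotype list strings, and translates
    typings locus-wise between field resolutions and G/P/g allele groups, so
    that heterogeneous registry-style typing records can be brought to a
    uniform resolution before estimation. Ships population simulators
    (combinatorial Hardy-Weinberg construction and random haplotype pairing),
    resolution heterogenization and allele-code masking for validation
    studies, a synthetic nomenclature fixture generator, and frequency-set
    comparison observables (distance, maximal absolute difference, first
    deviating rank, additional/missing haplotypes) plus a Hardy-Weinberg
    effect-size statistic.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
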