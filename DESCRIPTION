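Package: sweeplink
Title: Two-Locus Hitchhiking, Sweep Outlier Scans, and Fine Mapping of
    Linked Adaptive and Incompatibility Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying how selection on one locus drags tightly
    linked alleles to high frequency. Implements a deterministic two-locus
    hitchhiking model for hard and soft selective sweeps with an analytic
    hard-sweep solution; marker diversity summaries (allele counts, unbiased
    expected heterozygosity) and multiallelic Weir-Cockerham Fst with an
    island-model coalescent null (infinite-alleles mutation) for Fst outlier
    detection; backcross fine-mapping operators (recombinant calling and
    confirmation, breakpoint imputation, centimorgan estimation, interval
    localization of a second locus); hybrid-inviability assay analytics
    (per-line rates, bimodal carrier classification, rank-sum comparisons,
    reciprocal-cross asymmetry); and seeded synthetic-data generators that
    emulate the mapping, population-marker and inviability designs, so the
    whole pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
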