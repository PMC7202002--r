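Package: cladeqc
Title: Assembly QC, Haplotype Consensus and Enhancer Orthology for Clade
    Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for the bespoke computational stages of short-read
    clade-genomics resources: k-mer-spectrum genome profiling (genome size,
    coverage, de Bruijn variant/repeat branch frequencies), read preparation
    and contaminant screening (quality trimming, SSR detection, k-mer read
    filtering, GC-by-coverage scaffold gating), scaffold post-processing
    (gap splitting, hard masking, ambiguity resolution), assembly
    contiguity and completeness metrics (NG50, NG graphs, gene-sized
    fraction), phase-set majority-haplotype consensus calling from phased
    VCFs, UCSC-chain coordinate remapping with minMatch/multiple semantics,
    and reciprocal-best-hit enhancer orthology with alignment summary
    statistics. Includes a synthetic diploid genome, read, VCF, tile and
    chain simulator so the whole pipeline is testable without downloads,
    and bundles the published summary tables of the 23-genome Drosophila
    montium assembly resource the methods derive from.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    broom
Config/testthat/edition: 3
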