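Package: epigerm
Title: Germline Epigenomics of Transposable Elements: Binned DMR Calling,
    Repeat Expression, piRNA Classification and Chromatin Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the bespoke computational analyses
    used in germline epigenomics studies of transposable-element silencing:
    whole-genome bisulfite differentially methylated region (DMR) calling on
    fixed 500-bp bins with a two-sided Fisher exact test and Benjamini-Hochberg
    correction, matched random control-region sampling, fractional 1/n
    multi-mapper quantification of transposon-family expression, repeat
    consensus ("microgenome") methylation profiling, small-RNA piRNA
    annotation with 1U/10A primary/secondary classification, Tn5 cut-site
    corrected ATAC-seq and deduplicated ChIP-seq coverage profiles, and
    feature-overlap enrichment statistics. A seeded synthetic-data generator
    produces genomes, methylomes and read sets with known ground truth so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    withr,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
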