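Package: mirweed
Title: Small RNA Sequencing Analysis for miRNA Discovery in Herbicide-Resistant Weeds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, desk-scale pipeline for plant small RNA
    sequencing analysis: read cleaning and accounting, annotation of
    reads against non-coding RNA reference sets, conserved miRNA
    identification by mismatch-limited matching, novel miRNA prediction
    from hairpin (pre-miRNA) precursors folded under a simplified
    nearest-neighbor energy model with MIREAP-style duplex criteria,
    position-specific-rule miRNA target prediction, TPM normalization
    with fold-change differential expression calling, and qRT-PCR
    relative quantification by the 2^-ddCt method. Includes a synthetic
    data generator that plants hairpins, differential miRNAs, and
    contaminant reads into simulated libraries with ground-truth tables
    for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    S4Vectors,
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
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
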