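Package: mpragram
Title: Design and Analysis of Coupled Reporter and Epigenomic Profiling MPRA Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for lentiviral massively parallel reporter assay (MPRA)
    experiments that read out transcriptional activity (RNA/DNA barcode
    ratios) together with targeted epigenomic signal (UMI counts from
    ATAC or CUT&Tag enrichment of the integrated library). Generates
    synthetic-enhancer grammar libraries (homotypic, pairwise and
    four-motif permutation arrangements of transcription-factor motifs),
    saturation single-nucleotide substitution libraries, and 6-bp
    sliding-window perturbation libraries with a motif-creation rejection
    screen; counts barcodes and UMIs from read-level data with
    mismatch-free assignment and deduplication; computes CPM plus
    control-anchored TMM-normalized activity scores; and provides the
    downstream inference battery: motif copy-number trend tests, pairwise
    synergy regression with an interaction term, motif-order ANOVA,
    positional hypergeometric enrichment, variant-effect regression, and
    a MAD-score based one-dimensional Canny edge detector that calls
    functional sites from perturbation scans. A synthetic-data generator
    emulates the assay end to end so every stage is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    withr,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
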