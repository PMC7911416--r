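Package: rcnvseq
Title: Low-Pass Whole-Genome Sequencing Copy-Number Analysis for Prenatal Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for bin-based copy-number analysis of low-pass
    whole-genome sequencing data from prenatal samples: adapter trimming and
    sequencing quality-control indicators, fixed 20-kb binning of uniquely
    mapped reads, GC-stratified normalization to copy number, threshold-based
    CNV calling with mosaicism bands and ISCN-style nomenclature, concordance
    scoring of called intervals against microarray-defined truth, a maternal
    cell contamination gate, and a seeded count-level and read-level simulator
    so the whole pipeline is verifiable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
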