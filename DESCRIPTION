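Package: nmdmutscan
Title: NMD-Substrate Annotation, Differential Splicing, and Threshold
    Somatic Variant Calling for Candidate Driver Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for asking whether recurrently reported tumor
    mutations behave like pathogenic drivers or like standing germline
    variation, built around the analyses used to evaluate UPF1 variants in
    pancreatic adenosquamous carcinoma. Annotates transcript isoforms as
    nonsense-mediated mRNA decay (NMD) substrates with the 50-nt rule,
    enumerates co-linear splice junctions, quantifies alternative splicing
    (PSI) from isoform-discriminating reads and applies a threshold
    differential-splicing filter, performs matched tumor-normal
    threshold-based somatic variant calling with positive-control
    sensitivity calibration, matches reported mutations against population
    variant catalogs, and provides the cohort-level two-proportion tests.
    Includes synthetic-data generators that emit GTF, SAM, VCF and count
    tables with machine-readable ground truth so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    methods,
    BiocGenerics,
    GenomeInfoDb,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
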