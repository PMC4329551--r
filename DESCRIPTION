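Package: tfcr
Title: TFBS-Clustered Region Discovery and Integrative Regulatory Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calls transcription-factor-binding-site (TFBS) clustered
    regions genome-wide by Gaussian kernel density estimation with a
    kernel-weighted complexity score, categorises them into ten complexity
    classes with HOT/COLD flags, consolidates per-cell-type calls into a
    non-overlapping master list with genomic-class annotation, runs
    saturation analysis with Weibull extrapolation, aggregates signal
    density and tests peak enrichment with a segment-aware rotation null,
    quantifies nucleosome positioning by FFT power spectra and central
    depletion, infers cell-lineage dendrograms from binary region-presence
    matrices with Hungarian precursor placement, compares dendrograms via
    Baker's Gamma and Fowlkes-Mallows Bk, and summarises evolutionary
    conservation and nucleotide diversity. Ships a synthetic-data module
    that generates every input with known ground truth and a command-line
    entry point exposing each stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
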