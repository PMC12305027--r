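Package: goten
Title: Genotyping of Transcriptomes Enhanced with Nanopore Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Cell-type-informed genotyping of mosaic somatic variants in 10X
    single-nucleus RNA-seq cDNA from targeted long-read amplicons. Locates the
    cell-barcode/UMI cassette in noisy long reads, corrects barcodes against a
    whitelist, anchors read payloads to an amplicon reference to read out the
    variant allele, collapses reads to UMI consensuses with quality-aware
    error probabilities, calls each cell reference-homozygous or
    heterozygous-mutant with a Bayesian genotyper in high-specificity
    (Illumina-UMI-matched) or high-sensitivity mode, and tests per-cell-type
    mutant enrichment with hypergeometric tests and Benjamini-Hochberg
    correction. A simulator generates every pipeline input with known truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    Rsamtools,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
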