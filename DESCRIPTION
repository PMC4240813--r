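Package: indelqc
Title: Quality Classification and Concordance Analysis of INDEL Call Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for evaluating insertion/deletion (INDEL) call sets from
    short-read sequencing. Implements a k-mer Chi-Square allele-balance score
    with a three-tier (high/moderate/low) quality classification, left
    normalization of variant representations against a reference, exact-match
    and position-match concordance between call sets with coverage
    stratification, multiple-signature detection, homopolymer and short tandem
    repeat context annotation, coverage-uniformity statistics (bias-corrected
    coefficient of variation, coverage fraction at X reads), and a
    coverage-downsampling sensitivity analysis stratified by zygosity. A
    synthetic-data generator produces references with planted repeat tracts,
    truth INDEL sets, and platform-flavoured call sets (whole-genome-like,
    exome-capture-like) with planted error structure, so every analysis runs at
    desk scale without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
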