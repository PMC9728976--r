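Package: lncact
Title: Hit Calling and Signature Scoring for Pooled CRISPR Activation
    Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide CRISPR-activation
    (CRISPRa/SAM) coculture screens targeting long non-coding RNAs:
    exact-match spacer quantification from reads, pseudocount/total-count
    normalization and log2 fold changes with replicate QC, guide library
    reannotation against a genome and transcript annotation using
    strand-aware promoter windows (-1000/+100 of the TSS, at least two
    guides per target), gene-level ranking by a RIGER-style weighted rank
    statistic and by alpha-RRA with a nontargeting-control null, weighted
    replicate P-value combination and dual-method intersection hit
    calling. Also builds weighted transcriptional activation signatures
    from differential-expression tables, scores expression profiles with
    them, and provides the survival and multiplicity utilities used in
    downstream cohort association analyses. Includes seeded synthetic-data
    generators that emulate the statistical structure of such screens and
    cohorts for testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    survival,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
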