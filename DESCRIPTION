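Package: crest
Title: Context-Specific Regulatory Enhancer and Signature Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies context-specific transcription-factor target genes in
    tumors with constitutive NRF2 activation. Combines gene-set algebra over
    knockdown and induction differential-expression contrasts, classification
    of NRF2-dependent enhancers from paired H3K27ac coverage tracks, cofactor
    colocalization ranking by base-pair Jaccard with a permutation null, and
    signature-based transcription-factor activity scoring of expression
    cohorts. Ships seeded synthetic-data generators that plant every structure
    the pipeline infers, so the full analysis runs end-to-end without external
    downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
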