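Package: smacaller
Title: Detect Spinal Muscular Atrophy from Short-Read Sequencing Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects the most common molecular cause of spinal muscular
    atrophy (homozygous loss of functional SMN1) from exome, genome, or
    panel short-read alignments. Counts base observations at the shared
    c.840 position of the SMN1 and SMN2 paralogs, gates on read coverage,
    and classifies samples with a phred-scaled binomial likelihood-ratio
    rule whose decision boundary is linear in the (r, N) read counts.
    Includes a seeded synthetic-read simulator that emulates the
    near-identical paralog pair, a batch cohort runner with tab-separated
    output, and evaluation utilities (positive predictive value, no-call
    rate contrasts via Fisher's exact test, call-set concordance, and
    diagnostic scatter plots).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Rsamtools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
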