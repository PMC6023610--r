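Package: TALEreg
Title: Stage-Resolved Analysis of TALE Transcription-Factor Occupancy and
    Chromatin State
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing how TALE-family transcription factors (Prep,
    Pbx, Meis) occupy distinct DNA motif classes at different embryonic stages
    and how that occupancy relates to chromatin state and gene expression.
    Provides summit-based peak colocalization and stage-specific peak
    subtraction, IUPAC consensus motif scanning on both strands with
    nested-motif exclusion (DECA/HEXA semantics), reference-point signal
    matrices around peak summits, k-means chromatin-state classification
    (MPAD / Class 1-4), TSS-window peak-to-gene association with permutation
    enrichment and class-wise expression tests, delta-Ct qPCR quantification,
    and a synthetic-data generator that emulates the statistical structure of
    stage-resolved ChIP-seq experiments so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
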