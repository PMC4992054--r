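Package: racekit
Title: Targeted RACE Long-Read Sequencing Analysis and Transcript
    Boundary Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for targeted rapid-amplification-of-cDNA-ends (RACE)
    experiments read out by long-read sequencing. Covers the complete
    computational workflow: selection of lowly expressed target transcripts
    by RPKM and CAGE criteria, design of specificity-masked outer and
    nested RACE primers, adapter/quality/length preprocessing of long
    reads, splice-junction extraction with offset-entropy filtering,
    on-target enrichment accounting, clustering of transcription start and
    termination sites with novelty and CAGE/polyA-site support calls,
    inference of polyadenylation sites from non-templated read tails, and
    locus extension/merge bookkeeping. A deterministic simulator generates
    genomes, truncated annotations, primer panels, reads and evidence
    tracks with a machine-readable truth ledger so the whole pipeline can
    be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rcpp,
    methods,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
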