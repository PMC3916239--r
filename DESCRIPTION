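Package: wrescan
Title: Bipartite TCF/POP-1 Binding-Site Cluster Detection and Defecation
    Rhythm Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for locating candidate Wnt response elements (WREs) that
    are recognized by C-clamp-containing TCF transcription factors such as
    C. elegans POP-1. Builds and applies additive position weight matrices
    for the HMG and Helper DNA motifs, extracts fixed-length upstream
    promoter regions from a genome FASTA plus GFF3 annotation, detects
    clusters in which a 50-bp window holds at least two Helper sites and one
    HMG site, and classifies cluster topology and HMG-Helper pair
    orientation. A seeded synthetic-data generator plants motif clusters in
    background DNA with exact truth annotations, and a companion module
    summarizes defecation-cycle interval series (per-animal means, group
    statistics, percent change versus control, missed-expulsion rates, and
    Student's two-tailed t tests).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
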