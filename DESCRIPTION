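Package: teclusterkit
Title: Detection and Population Analysis of Recurrent Transposable
    Element Insertion Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing recurrent transposable element (TE)
    insertions in gene promoter regions across many resequenced or
    PCR-screened strains. Normalises per-strain insertion calls to
    canonical sites (midpoint plus 5-bp collapse), scans the genome for
    insertional clusters in 1-kb windows and in strand-aware promoter
    regions (1 kb upstream of the TSS plus the 5'UTR), summarises
    multi-population insertion catalogues (allele frequencies, occupancy,
    private insertions, expected co-occurrence, latitude and climate
    association), detects target site duplications (TSDs) from paired
    occupied/empty allele sequences and profiles their consensus, groups
    identical element copies as transposition-burst candidates, and
    estimates by Monte-Carlo strain subsampling (with a closed-form
    check) how many distinct insertions a small screen detects. A
    ground-truthed synthetic data generator emulates multi-strain screens
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
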