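Package: clusterscout
Title: Detection of Metabolic Gene Clusters and Tandem Duplications with
    Mutual-Rank Co-Expression Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans genome annotations for neighborhoods of signature
    enzyme-family genes (cytochrome P450, 2-oxoglutarate-dependent
    dioxygenase, terpene synthase, polyketide synthase,
    UDP-glycosyltransferase), classifies them as candidate multi-family
    metabolic gene clusters or single-family tandem-duplication arrays,
    and screens the candidates with an ATTED-II-style mutual-rank
    co-expression network to flag co-regulated neighboring-gene clusters.
    Includes a seeded synthetic-data generator that plants clusters,
    tandem arrays and latent co-regulation modules with recoverable
    ground truth, so the whole pipeline is testable without external
    genome or transcriptome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
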