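Package: mobsplice
Title: Screening Polymorphic Mobile-Element Insertions for Effects on mRNA Splicing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to screen polymorphic transposable-element insertion
    variants (such as Alu elements) for effects on mRNA splicing.
    Implements exon-proximity profiling of intronic insertion variants
    with depletion-zone quantification near exons, candidate
    prioritization within a configurable window of alternatively used
    exons (with frameshift, orientation and position annotation and the
    associated chi-square enrichment tests), design of control sequences
    for minigene splicing reporters (scrambled elements and GC-matched
    randomized spacers), length-normalized quantification of splice
    isoforms from gel or fragment-analyzer band tables and from qPCR Ct
    tables, and genotype-dose splicing-QTL statistics with family-wise
    Bonferroni correction. A synthetic-data generator produces annotation,
    insertion catalogs, band tables, Ct tables and genotype panels with
    known ground truth so every stage of the pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
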