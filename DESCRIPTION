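Package: ltrdyn
Title: Detection, Dating and Expression Dynamics of Full-Length LTR Retrotransposons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural detection of full-length LTR retrotransposons (paired
    long terminal repeats with target-site duplications), redundancy clustering,
    protein-domain based superfamily/lineage annotation, insertion-age dating
    from Kimura two-parameter LTR divergence, read-mapping genomic abundance,
    RPKM expression quantification with negative-binomial differential
    expression calls, gene-proximity expression category tests and GO
    enrichment, and per-lineage ANOVA/regression trend analyses. Includes a
    synthetic-genome and read simulator with planted elements of known age,
    lineage and expression so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
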