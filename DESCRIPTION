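Package: gbmkit
Title: Gene Body Methylation and Transcriptome Integration for Insect
    Embryo Bisulfite and RNA-Seq Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for whole-genome bisulfite sequencing and
    stage-resolved RNA-seq of insect embryos with gene body methylation,
    modelled on knockdown studies of maintenance DNA methyltransferases
    during the maternal-zygotic transition. Provides per-CpG methylation
    calling by an exact binomial test against the bisulfite non-conversion
    rate, gene-body fractional methylation and bimodal methylated-gene
    classification, metagene profiles, two-group beta-binomial differential
    methylation with per-mCG depletion statistics, a simplified
    negative-binomial Wald differential-expression engine with
    median-of-ratios normalization, and the integration statistics linking
    methylation loss to expression change (contingency tests, rank
    correlation, trajectory clustering). A seeded synthetic-data generator
    emulates the statistical structure of such experiments so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
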