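Package: epidmr
Title: Differential DNA Methylation Regions and Methylation Modules for
    MeDIP-Seq Transgenerational Disease Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Window-based analysis of MeDIP-Seq sperm methylation data for
    studies of environmentally induced transgenerational disease. Tiles the
    genome into fixed windows, counts aligned fragments, tests two-group
    differential coverage with a negative-binomial exact test under a common
    dispersion, calls differential DNA methylation regions (DMRs) by seed
    thresholding with edge extension, associates DMRs with nearby gene
    models, compares DMR sets across exposures and diseases (Venn overlap,
    asymmetric extended overlap, chromosomal cluster scan), detects
    correlated methylation modules via topological overlap and relates
    module eigengenes to sample traits, and classifies animals as diseased
    from multi-observer histopathology abnormality counts. Includes a
    seeded synthetic-data generator that emulates the statistical structure
    the analysis assumes, so the whole pipeline can be exercised end to end
    with planted signal.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    edgeR,
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
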