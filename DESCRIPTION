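Package: aipqtl
Title: Extreme QTL Mapping and Quantitative Genetics for Advanced
    Intercross Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping quantitative trait loci by pooled
    sequencing of phenotypic extremes (extreme QTL / bulk-segregant
    designs) in multiparental advanced intercross populations, with a
    forward-in-time simulator of the full experimental design.  Includes
    balanced-ANOVA variance partitioning and broad-sense heritability for
    inbred line panels, tolerance scoring for repeated-exposure assays, a
    pooled allele-frequency Z test with Bonferroni thresholds, simplified
    line-mean association tests, candidate-gene overlap statistics with a
    permutation null, one-linker interaction-subnetwork extraction, and
    qPCR delta-Ct expression comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
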