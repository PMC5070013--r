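Package: xdosage
Title: Dosage Compensation Analysis of X Chromosome Condensation,
    H4K16 Acetylation and Expression in C. elegans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative pipeline for studying X chromosome dosage
    compensation in Caenorhabditis elegans. Measures chromosome-territory
    occupancy and probe-pair 3D distances from multi-channel FISH image
    stacks, performs ploidy-aware normalization, z-scoring, broad-peak
    calling and genomic-category annotation of H4K16ac ChIP-seq coverage,
    computes gene-anchored metagene profiles, and derives chromosome-level
    expression-skew statistics (X:A ratios, shift tests, quadrant
    concordance). A synthetic-data module generates every input the
    pipeline consumes (nucleus stacks, probe-spot stacks, ChIP read sets
    with planted enrichment islands, negative-binomial count tables) with
    configurable effect sizes, so every stage is testable end to end by
    parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    tiff,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
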