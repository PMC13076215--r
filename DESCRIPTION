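Package: chromstate
Title: Promoter Chromatin State Quantification and Classification from
    ChIP-seq Signal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies RNA polymerase II, Ser2-phosphorylated Pol II and
    histone-mark (H3K4me3, H3K27me3) ChIP-seq signal at gene promoters and
    gene bodies as background-corrected RPKM, using the mean upstream
    (-4 to -3 kb) signal across genes as a per-sample background
    coefficient. Classifies promoters into chromatin states by fixed
    normalized-signal thresholds: bivalent (with Pol II positive or
    negative sub-states), activated, silenced, transcriptionally decoupled
    (elongating Pol II without mRNA output) and germ-layer-specific.
    Stratifies bivalent promoters into strong/weak chromatin clusters,
    provides k-means clustering under an uncentered-correlation distance,
    tracks gained/lost Pol II-positive promoters and mark-onset cascades
    across developmental stages, and computes knockout fold-change
    quadrant statistics. Includes a seeded synthetic ChIP-seq study
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
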