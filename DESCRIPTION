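Package: sumopipe
Title: Chromatin deSUMOylation Analysis Toolkit: Peak Calling, Regulatory
    Annotation, 4C-seq Viewpoint Profiling and SUMOylome Accounting
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements an integrated analysis pipeline for studying
    drug-induced chromatin deSUMOylation in acute myeloid leukemia models:
    a threshold/max-gap/min-run peak caller for fixed-bin signal tracks
    (SUMO-2/3 ChIP-seq, CTCF CUT&RUN), histone-mark based promoter and
    candidate-enhancer annotation with metaprofiles and ranked heatmap
    matrices, interval-set algebra and gene-list crossing, a complete
    4C-seq viewpoint pipeline (capture filtering, in-silico restriction
    fragment maps, fragment counting, per-million normalization,
    replicate-consistent interaction calling and differential contact
    testing), SILAC SUMOylome log2-ratio classification with
    inclusion-exclusion set accounting, and a compact negative-binomial
    differential expression stage with Benjamini-Hochberg control. A
    synthetic-data generator with planted ground truth makes every stage
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
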