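Package: SweepNet
Title: Case/Control Selective-Sweep Scanning and Signed Co-Expression
    Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Windowed selection scans for case/control resequencing panels
    (per-site and 40-kb windowed FST and nucleotide diversity, delta-Pi,
    top-quantile candidate intersection, control-subsampling recovery-ratio
    validation, and a genotype-frequency highly-differentiated-site filter),
    together with a bulk transcriptomic arm (FPKM, expressed-gene filtering,
    log2 normalization with optional GC/length correction, per-gene
    covariate removal, linear-model differential expression with FDR
    control, multi-method intersection) and a signed weighted co-expression
    network (soft-power selection by scale-free fit, topological overlap,
    module detection and merging, module eigengenes, module-trait
    correlation, and GS/kME/connectivity hub-gene selection with
    thresholded edge export). A seeded synthetic-data module generates
    genotype and expression inputs with planted ground truth so every stage
    is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    limma,
    vcfR,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
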