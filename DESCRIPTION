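Package: fibroscore
Title: Activation Scoring and Multi-Omics Target Prioritization for Cardiac Fibroblasts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the quiescent-to-activated transition of cardiac
    fibroblasts from paired bulk transcriptome and proteome profiles. Implements a
    marker-panel summed z-score activation score with two-way ANOVA/Tukey group
    testing, median-of-ratios count normalization, total-area protein normalization,
    moderated-t differential expression with layer-specific decision rules,
    transcript-protein fold-change integration (correlation, location prevalence,
    correlation-distance clustering, PCA), hypergeometric term enrichment, a
    sign-consistency upstream-regulator z statistic, and a disease-association plus
    interaction-network target-prioritization cascade. A seeded synthetic-data
    generator emulating a three-source, two-condition, three-replicate design with
    known ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    ape,
    withr
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
biocViews: Transcriptomics, Proteomics, DifferentialExpression, GeneExpression,
    NetworkInference, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'activation.R'
    'annotate.R'
    'crossomics.R'
    'diffexpr.R'
    'io.R'
    'pipeline.R'
    'prioritize.R'
    'simulate.R'
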