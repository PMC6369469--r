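Package: lncnet
Title: Two-Group lncRNA/mRNA Microarray Analysis and Coexpression
    Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis pipeline for two-group (case/control)
    lncRNA and mRNA expression microarrays: quantile normalization,
    fold-change and t-test differential-expression screening with
    hierarchical clustering, qPCR 2^-ddCt concordance checks, signed
    Pearson lncRNA-mRNA coexpression networks, hypergeometric
    guilt-by-association functional annotation of lncRNAs, and
    transcription-factor association networks built from TF-target gene
    sets. Includes a synthetic-data generator with planted ground truth
    (differential expression, latent-factor coexpression modules, and
    TF-module links) for validating every stage, and exporters to
    Cytoscape-readable SIF, GraphML and edge-table formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    limma,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
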