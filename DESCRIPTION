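Package: CoexCircuits
Title: Signed Gene Coexpression Networks Across Brain Regions with
    Cross-Species Module Conservation and Circuit Hypotheses
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end systems-genomics pipeline for multi-region brain
    expression studies of selectively bred lines: detection filtering,
    normalization and outlier handling; empirical-Bayes moderated-t
    differential expression with excess-DEG chi-square tests; signed weighted
    gene coexpression network construction (soft-threshold adjacency,
    topological overlap, average-linkage clustering with a dynamic tree cut);
    module eigengenes, intramodular connectivity and hub/hub-module statistics;
    module characterization by DEG over-representation, cell-type marker
    enrichment and eigengene region ANOVA; cross-species module-conservation
    meta-networks over ortholog maps; and ranked neural-circuit hypotheses from
    multi-region module coregulation. A synthetic-data generator with known
    ground truth emulates the 2-genotype x 7-region x 12-replicate study design
    so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
biocViews: GeneExpression, Network, DifferentialExpression, Microarray
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
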