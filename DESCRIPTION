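Package: ilpnet
Title: Phenotype Screening and Regulatory Network Analysis for the C. elegans
    Insulin-Like Peptide Family
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for mapping a family of insulin-like
    peptide (ILP) genes to phenotypes and to each other. Implements multi-trial
    phenotype confidence calling (right- and interval-censored log-rank tests,
    exact hypergeometric count tests, chi-square and binomial-GLM trial
    combination), inference of a directed signed ILP-to-ILP regulatory network
    from perturbation qPCR (geNorm reference stability, geometric-mean
    normalization, linear-model differential tests, Storey q-values,
    allele-aware edge calling), graph-theoretic characterization (path length,
    clustering, centralities, Humphries small-worldness, edge-perturbation rank
    robustness), Barber bipartite modularity with adaptive BRIM and two null
    models, and classification of double-mutant genetic interactions from
    dauer-entry counts. Ships synthetic-data generators with known ground truth
    for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    survival,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
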