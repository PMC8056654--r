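Package: dignet
Title: Network-Based Discovery of Adverse-Event-Associated Drugs, Gene
    Modules and Biomarker Panels
Version: 0.1.0
Authors@R:
    person("dignet", "developers", email = "dignet@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for linking adverse drug
    events to molecular mechanism: disproportionality mining of
    spontaneous-report databases (reporting odds ratios with Fisher
    significance), selection of representative drug-perturbation
    expression profiles, a from-scratch weighted gene co-expression
    core (soft-threshold adjacency, topological overlap, average
    linkage clustering with a static tree cut, module eigengenes and
    eigengene merging), gene-set over-representation, hub extraction
    by Maximal Clique Centrality and betweenness on protein-protein
    interaction graphs, group-label permutation tests, univariate
    logistic odds-ratio plus ROC/AUC biomarker ranking, and chemical
    diversity summaries (Tanimoto similarity, coefficient of
    variation).  A synthetic-data generator plants recoverable
    structure in every input so each stage is verifiable at desk
    scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
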