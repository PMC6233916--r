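Package: crdnet
Title: Component-Resolved IgE Networks and Differential Interaction
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multiplex component-resolved allergy
    diagnostics (ISAC) data in relation to childhood asthma. Provides
    ingestion and filtering of specific-IgE (ISU) matrices, clustering of
    allergen components by distance correlation with average-linkage
    hierarchical clustering (plus DIANA and PAM comparators and Rand-index
    agreement), clustering of participants on binary sensitisation
    profiles with Jaccard distance and Ward linkage with Calinski-Harabasz
    model selection, cluster-outcome association statistics, the JDINAC
    joint-density differential interaction network classifier (per-pair
    class-conditional kernel densities, log density-ratio features,
    class-weighted L1 logistic regression with multiple splitting and
    prediction averaging), a penalised logistic regression baseline with a
    repeated cross-validation evaluation harness, bipartite
    group-component network views, and a synthetic zero-inflated
    Gaussian-copula cohort generator with planted component blocks and
    class-conditional differential dependencies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    cluster,
    glmnet,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
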