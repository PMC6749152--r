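Package: circeNet
Title: Circular RNA-Associated Competing Endogenous RNA Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Construction and dissection of circRNA-associated competing
    endogenous RNA (ceRNA) networks from two-condition expression profiles
    and miRNA-target interaction tables. Provides empirical-Bayes moderated
    t-statistics with method-of-moments hyperparameter estimation, signed-z
    (Stouffer) meta-combination of differential expression evidence across
    datasets, shared-miRNA ceRNA crosstalk enumeration, disease subnetwork
    extraction and risk-crosstalk prioritization of circRNAs, degree
    distribution and power-law diagnostics, hypergeometric
    over-representation analysis with Benjamini-Hochberg correction, and a
    seeded synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    igraph,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: NetworkInference, DifferentialExpression, GeneSetEnrichment,
    Network, SystemsBiology
RoxygenNote: 7.3.3
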