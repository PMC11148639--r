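Package: immunoModules
Title: Multi-Omic Immune Module Discovery and Response Stratification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates serum proteomics, bulk tumor transcriptomics, and
    mass-cytometry summary statistics into a harmonized immune feature table;
    discovers correlated immune modules by Spearman-correlation network
    clustering (Ward linkage on the distance 1 - rho^4, silhouette-selected
    module count) and summarizes each module by the first principal component
    of its Z-scored members; stratifies patient groups with out-of-bag-tuned
    random forests using a ten-seed Gini-importance stability procedure; and
    provides the companion statistics: Wilcoxon/Fisher differential testing
    with Benjamini-Hochberg correction and a combined significance rule,
    Z-score stratification, per-feature Mahalanobis outlier attribution, and
    T cell receptor repertoire metrics (neoplastic clone identification,
    Gini-Simpson diversity, Morisita-Horn similarity, differential clone
    abundance). A synthetic cohort generator with planted correlation blocks,
    group effects, censoring and dominant clones makes every stage testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    cluster,
    ranger,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
biocViews: Classification, Clustering, ImmunoOncology, Proteomics,
    Transcriptomics, SingleCell
RoxygenNote: 7.3.3
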