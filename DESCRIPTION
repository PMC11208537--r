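Package: paddynet
Title: Pollution Indices, Bacterial Diversity and RMT-Thresholded
    Co-Occurrence Networks for Metal-Polluted Paddy Soils
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for soil microbiome surveys of heavy-metal
    polluted paddy fields: contamination factors and the pollution load
    index with pH-dependent cadmium risk screening, alpha-diversity
    estimators (Chao1, ACE, Shannon, Good's coverage), Bray-Curtis
    dissimilarity and NMDS ordination, environment-community association
    statistics (polynomial regressions, Spearman grids, Mantel and partial
    Mantel permutation tests, variation partitioning, random-forest
    importance), and Pearson co-occurrence networks thresholded by a
    random-matrix-theory (RMT) criterion with greedy modularity, degree-
    preserving null ensembles and Zi-Pi keystone-role classification.
    A synthetic-data generator plants known module structure and a pH-like
    gradient so every stage is verifiable against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    vegan,
    igraph,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    xml2,
    biomformat
Config/testthat/edition: 3
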