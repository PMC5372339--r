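Package: cocaclust
Title: Multi-Level Cluster-of-Clusters Integration of Tumor Classifications
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates categorical tumor classifications from multiple
    molecular levels (mRNA subtypes, protein subtypes, copy-number complexity
    groups, microRNA clusters, metabolic clusters and combined-platform
    clusters) into higher-order consensus subtypes by cluster-of-clusters
    analysis (COCA).  Provides the single-level classifiers feeding the
    integration (nearest-centroid subtyping with cohort re-centering, nearest
    shrunken centroids, complex arm aberration index grouping, recursive
    partitioning with the gap statistic, metabolic spectrum preprocessing and
    hierarchical clustering), resampling-based consensus clustering on a
    missingness-normalized Manhattan distance with silhouette-based selection
    of the number of clusters, phi-coefficient association ranking of subtype
    levels against consensus clusters, derivation of discriminating expression
    signatures (rank tests with false discovery rate control, correlation
    filtering, Fisher gene-set enrichment), Kaplan-Meier/log-rank/Cox survival
    validation of a signature-based split, and a synthetic multi-level cohort
    generator for end-to-end testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    jsonlite
Config/testthat/edition: 3
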