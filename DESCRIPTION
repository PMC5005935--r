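Package: cytotemplates
Title: Template-Based Matching and Classification of Flow Cytometry Samples
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Cross-sample analysis of flow cytometry data built on cluster
    matching. Samples are variance-stabilized with an asinh transformation
    whose cofactor minimizes Bartlett's statistic over one-dimensional
    density-peak clusters, partitioned into cell populations by k-means with
    the number of clusters chosen by a consensus of five validity indices,
    and summarized as Gaussian clusters. Populations are registered across
    samples with a minimum-cost mixed edge cover under Mahalanobis,
    symmetrized Kullback-Leibler or Euclidean-center dissimilarities; the
    cover cost defines a sample dissimilarity used to build hierarchical
    matching-and-merging template trees whose internal nodes hold
    meta-clusters estimated by maximum likelihood. Templates support
    nearest-template classification, dynamic sample insertion, detection of
    disease-specific meta-clusters, and a piecewise scoring function for
    leukemia-type cohorts where a minority class carries extra blast-like
    populations. A synthetic-cohort generator with ground-truth labels at
    every level makes the whole pipeline testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    MASS,
    cluster,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
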