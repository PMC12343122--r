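Package: chasecluster
Title: Chase Clustering and Constrained Ward Analysis of Presence-Absence
    Community Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Compositional clustering of site-by-species incidence matrices.
    Implements unconstrained "chase" clustering, a seeded, penalized,
    multi-start stochastic partition optimizer that infers the number of
    clusters endogenously from a pairwise similarity ("chase") matrix; a
    geography-constrained Ward hierarchical clustering built on a convex
    alpha-combination of compositional and great-circle dissimilarities with
    inertia-based alpha selection; adjusted-Rand comparison of partitions;
    Jaccard faunal turnover between epochs at radius-aggregated localities;
    and a planted-partition synthetic community generator for end-to-end
    validation. Designed for zooarchaeological and macroecological
    presence-absence data but applicable to any incidence matrix with site
    coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    geosphere,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
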