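Package: covnet
Title: Anatomical Covariance Network Analysis of Regional Gray-Matter Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Group-level anatomical covariance network analysis for regional
    gray-matter volume tables. Builds Pearson correlation (structural
    covariance) networks per group, binarizes them across a grid of network
    densities, computes global and nodal graph metrics (clustering,
    characteristic path length, global and local efficiency, small-worldness
    against degree-preserving null networks, modularity, betweenness
    centrality, degree), identifies betweenness-centrality hubs at standard
    deviation thresholds, quantifies resilience to targeted attack and random
    failure, and compares groups with one-tailed permutation tests on
    area-under-the-curve summaries plus FDR-corrected regional comparisons.
    Includes a synthetic-data generator with plantable covariance structure
    for validation, and the clinical outcome statistics that accompany such
    studies (one-way ANOVA, Pearson chi-square, paired t, outcome
    proportions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    MASS,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
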