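Package: plasmaselect
Title: Supervised Class Comparison and Class Prediction for Plasma miRNA Arrays
Version: 0.1.0
Authors@R: person("plasmaselect", "developers", role = c("aut", "cre"),
    email = "plasmaselect@example.org")
Description: End-to-end supervised analysis of plasma circulating miRNA
    hybridization-array data: case-control cohort construction by
    propensity-score caliper matching, detection-based feature filtering and
    ratio normalization, class comparison by a combined t-test /
    Anderson-Darling union rule under Benjamini-Hochberg FDR control,
    bootstrap feature ranking by simultaneous selection of three machine
    learning algorithms (nearest shrunken centroids, Boruta random forests,
    Elastic SCAD support vector machines) with co-occurrence networks, and
    leave-one-out cross-validated linear SVM classifier selection by Youden
    index and parsimony. Includes a synthetic-cohort generator emulating
    hemolysis-driven deregulation for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
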