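Package: conncog
Title: Structural Connectome Group Analysis and Classification for
    Multiple Sclerosis Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for FA-weighted structural brain networks in
    multiple sclerosis. Simulates cohorts of healthy volunteers and
    cognitively preserved or impaired patients with group-wise attenuation
    of connections at vulnerable nodes; filters edges by healthy-cohort
    prevalence and regresses age and sex confounds from edge weights;
    computes five nodal graph measures (strength, degree, local efficiency,
    clustering coefficient, betweenness centrality) on weighted undirected
    networks; runs per-node three-group statistics with normality and
    homoscedasticity gating and multiple-comparison correction; and
    classifies subjects with an ensemble of balanced-undersampled RBF
    support vector machines under stratified k-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    e1071,
    car,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
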