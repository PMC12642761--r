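Package: adbcascade
Title: Generalized Biomarker Cascade Modelling of Alzheimer's Disease on Brain Connectivity Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a spatiotemporal generalization of the Alzheimer's disease
    biomarker cascade model: coupled logistic ordinary differential equations
    for amyloid-beta, tau, neurodegeneration and cognition with graph-Laplacian
    diffusion on a 68-region functional-connectivity brain graph. Provides
    construction of population and patient-specific graphs (rank-2 low-rank
    perturbations of a population adjacency), a four-stage hierarchical
    parameter-inference pipeline with homotopy-regularized constrained
    optimization, variance-based (Sobol) global sensitivity analysis at two
    levels (parameter screening over age and regional/lobe interaction
    analysis), and a synthetic longitudinal cohort generator for parameter
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
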