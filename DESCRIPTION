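Package: bilatnet
Title: Joint Latent-Space Modeling of Brain Connectivity and Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generative Bayesian latent-space modeling of participant-level
    symmetric brain-connectivity networks jointly with multivariate behavioral
    outcomes. Each brain region receives a unidimensional latent position and
    edges are driven by bilinear products of positions; behavior follows a
    Rasch-type item model with a per-person latent trait. A joint multivariate
    normal prior couples the two latent spaces, so region-level cross
    covariances between connectivity and behavior become the imaging
    biomarkers of interest. Estimation is by a conjugate Gibbs sampler with
    reflection-sign alignment and multi-start selection. Includes a
    simulation-study generator, credible-interval biomarker reports with
    power/specificity scoring, out-of-sample prediction of behavior from
    connectivity and vice versa, connectome-based predictive modeling, lasso
    and canonical-correlation baselines, and weighted-graph topology
    statistics (strength, shifted closeness, betweenness).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    glmnet,
    igraph,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
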