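Package: ltnbayes
Title: Logistic-Tree Normal Models for Microbiome Compositional Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generative modelling of microbiome OTU/ASV count tables with the
    logistic-tree normal (LTN) model: the multinomial sampling model is
    decomposed into binomials along a rooted full binary phylogenetic tree and
    the node-level log-odds are modelled jointly as a multivariate Gaussian.
    Provides tree-based (tlr), isometric (ilr) and centred (clr) log-ratio
    transforms, exact Devroye-type Polya-Gamma data augmentation, blocked
    Gibbs samplers with a Bayesian graphical-lasso prior on the precision
    matrix, a mixed-effects model for differential abundance testing with
    spike-and-slab priors and posterior-expected-FDR node selection, and
    simulation generators (logistic-normal hub/block/sparse precision models,
    Dirichlet-tree multinomial, signal injection) with loss-based evaluation
    of estimated clr correlation matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
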