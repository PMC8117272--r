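Package: reachdist
Title: Stochastic Distance Modeling of Upper-Limb Reaching Movements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies how far impaired reach-to-grasp movements deviate
    from reference movement patterns.  Elbow-angle trajectories are
    low-pass filtered, segmented by a velocity-threshold rule, scaled to a
    common spatiotemporal frame, resampled by Gaussian-kernel regression,
    and summarised as two-dimensional Gaussian mixture models fitted by
    expectation-maximization with the model order chosen by the Bayesian
    information criterion.  Fitted models are compared with the
    bidirectional Kullback-Leibler divergence (variational approximation)
    and Hellinger's distance (unscented transform), scored against a set
    of reference models by the nearest-neighbour rule.  Also provides the
    standard clinical kinematic measures of reaching, tonic stretch
    reflex threshold estimation from dynamic threshold data, and a
    synthetic cohort generator emulating healthy and stroke-like reaching
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
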