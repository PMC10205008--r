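Package: flynav
Title: Temporal Novelty Detection and Two-Timescale Integration in Walking Fly Olfactory Navigation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative modelling of Drosophila orientation dynamics under
    temporally structured (fictive) odor stimuli. Builds square-wave odor
    protocols, computes onset-novelty and offset response kernels together with
    intermittency, frequency, dual and two-timescale integrating filters,
    simulates turn events as an inhomogeneous Poisson process with
    signal-dependent turn speeds and a sigmoidal upwind bias, and provides the
    matching estimation machinery: point-process maximum likelihood for the
    turn rate, Gamma and exponential likelihoods for turn speed and duration,
    least-squares baseline-bias fitting, simulation-based grid search for the
    bias kernels, and normalized-residual model scores. Includes turn
    segmentation with threshold calibration, sliding-window estimators with
    bootstrap errors, a synthetic tracked-trajectory generator, the closed-form
    asymptotic analysis of the two-timescale integrator, and agent-based
    simulations of plume navigation with Gaussian-packet plumes and
    Hassenstein-Reichardt odor-motion sensing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    minpack.lm,
    mclust
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
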