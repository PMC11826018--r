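Package: faeddm
Title: Hierarchical Drift Diffusion Analysis of Gender Face Aftereffect Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of two-group gender face-aftereffect
    choice/reaction-time experiments. Provides a Wiener first-passage-time
    likelihood kernel with exact trial simulators, a synthetic experiment
    generator with contaminant trials, the standard trial- and
    participant-level exclusion chain, model-free analysis (response
    proportions, aftereffect curves, and a 2 x 2 x 4 mixed ANOVA with
    Greenhouse-Geisser correction), a hierarchical Bayesian drift diffusion
    model fitted by a Metropolis-within-Gibbs sampler with split-chain
    convergence diagnostics, posterior contrast testing with false discovery
    rate adjusted credible intervals, posterior predictive checks, and a
    parameter-recovery harness, tied together by a reproducible pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    car,
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
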