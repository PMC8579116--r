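Package: statedcm
Title: State-Dependent Effective Connectivity from Resting-State Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates state-dependent effective (directed) connectivity from
    multichannel resting-state fMRI time series. Brain connectivity states are
    identified with a hidden Markov model over multivariate-autoregressive
    observations; effective connectivity is estimated per sliding window by
    inverting a spectral dynamic causal model (linearised neural dynamics with a
    hemodynamic observation model) against the windowed cross-spectral density;
    window-wise estimates are decomposed into state-specific components with a
    hierarchical parametric-empirical-Bayes scheme, including Bayesian model
    reduction, group contrasts, window-size selection by log Bayes factor, and
    subtyping of individuals by modularity clustering of their state-occupation
    patterns. A forward simulator of state-switching linear neural dynamics with
    a balloon-model hemodynamic readout generates synthetic datasets for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
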