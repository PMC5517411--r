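Package: longdcm
Title: Longitudinal Effective Connectivity by Spectral DCM and
    Parametric Empirical Bayes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for longitudinal analysis of directed (effective)
    connectivity in resting-state fMRI. Simulates multi-subject,
    multi-session BOLD time series from linear stochastic neural networks
    with scale-free fluctuations and Balloon-Windkessel haemodynamics;
    conditions the series (initial-volume discard, confound regression,
    detrending, frequency filtering, principal eigenvariates); estimates
    per-session effective connectivity by spectral dynamic causal
    modelling, i.e. variational Laplace inversion of a generative model of
    cross-spectral densities; and recovers group-level session effects and
    symptom-score associations with a two-level parametric empirical Bayes
    scheme and a 95 percent credible-interval non-zero criterion.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
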