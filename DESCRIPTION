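Package: caratlas
Title: Bayesian Small-Area Disease Mapping with Leroux CAR Smoothing and
    Uncertainty Visualization
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits Bayesian spatial smoothing models for small-area cancer
    statistics: standardized incidence ratios (SIR) via a Poisson likelihood
    and excess hazard ratios (EHR) via a piecewise-constant excess-hazard
    likelihood, both with a Leroux conditional autoregressive (CAR) prior on
    the spatial random effects, fitted by Metropolis-within-Gibbs MCMC.
    Posterior draws are summarized into posterior medians, 60%/80%
    equal-tailed credible intervals, and the posterior probability that an
    area differs from the national average (PPD). Includes the atlas-style
    uncertainty encodings as testable specification objects and reference
    renderers: the wave plot (log-scale posterior density with ratio-scale
    axis labels), the V-plot (estimate versus folded confidence), and
    PPD-driven choropleth transparency, plus grouped estimate overviews.
    A synthetic lattice data generator and a command-line pipeline make every
    stage reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    ggplot2,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
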