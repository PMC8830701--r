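Package: crninfer
Title: Sparse Bayesian Inference of Mass-Action Reaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies mass-action biochemical reaction networks from noisy
    time-series species concentrations. Candidate reactions are enumerated
    from templates into an ansatz library; a regularized-horseshoe shrinkage
    prior over reaction rates is combined with a latent-ODE log-normal (or
    Poisson) observational model and sampled with a gradient-based No-U-Turn
    sampler using forward ODE sensitivities; negligible reactions are pruned
    by a posterior scale rule and the recovered networks are reported with
    credible intervals and posterior-predictive trajectory bands. A
    derivative-based sparse-regression baseline (non-negative mixed l1/l2
    fit to finite-difference derivative estimates) is included for
    comparison.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
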