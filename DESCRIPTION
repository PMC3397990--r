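Package: grndesign
Title: Profile-Likelihood Experimental Design for Gene Regulatory Network
    ODE Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calibrates Hill-kinetics gene regulatory network ODE models by
    maximum likelihood under a clipped absolute-plus-relative Gaussian error
    model, assesses parameter identifiability with profile likelihoods, and
    selects maximally informative perturbation experiments by propagating
    profile-derived parameter uncertainty into trajectory spread under a
    credit-budget constraint. Includes a stiff Rosenbrock ODE integrator with
    forward sensitivity equations, latin-hypercube multi-start estimation in
    log-parameter space, likelihood-based confidence intervals, and a
    virtual-laboratory simulator (hidden truth parameters, noisy data
    vending, gel-shift measurements, credit ledger) for benchmarking design
    strategies offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
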