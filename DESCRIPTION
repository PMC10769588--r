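Package: idealobserver
Title: Markov Chain Monte Carlo Estimation of the Bayesian Ideal Observer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for task-based assessment of imaging systems via the
    Bayesian ideal observer (IO) in signal-known-exactly /
    background-known-statistically detection tasks.  Estimates the IO
    likelihood ratio by Metropolis-Hastings sampling: conventional chains
    over lumpy-background object parameters and generalized latent-space
    chains with preconditioned Crank-Nicolson proposals over any generative
    object model with a standard-normal latent space.  Includes stochastic
    object models (lumpy background, Gaussian signal, analytic latent
    generators), virtual imaging operators (Gaussian point-response-function
    collimator, undersampled k-space with variable-density Poisson-disc
    masks), reference observers (Hotelling observer by covariance
    decomposition, closed-form and brute-force IO oracles), convergence
    diagnostics (potential scale reduction factor, autocorrelation), and
    empirical ROC/AUC evaluation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
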