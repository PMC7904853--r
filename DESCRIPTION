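Package: divsmc
Title: Bayesian Comparison of Diversification Models by Sequential Monte Carlo
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative implementations of nine birth-death diversification
    models (constant-rate birth and birth-death, time-dependent variants,
    ClaDS0-ClaDS2, LSBDS and BAMM) as weighted simulations along an observed
    time-calibrated phylogeny, together with the sequential Monte Carlo
    machinery needed to estimate their marginal likelihoods: aligned
    resampling at observed speciation events, delayed (conjugate) sampling of
    rate parameters, the alive particle filter, and importance sampling
    against closed-form likelihoods. Includes analytic and simulation oracles
    for the constant-rate and time-dependent birth-death processes, forward
    simulators for all models, posterior summaries as mixtures of conjugate
    distributions, and Bayes-factor model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
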