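Package: conflictdm
Title: Diffusion Models for Conflict Tasks: Densities, Fitting, and
    Parameter Recovery
Version: 0.1.0
Authors@R:
    person("Conflict", "DM Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Time-inhomogeneous drift-diffusion models for conflict tasks
    (Simon, Eriksen flanker): the Diffusion Model for Conflict tasks (DMC),
    whose automatic channel follows a rescaled Gamma pulse, and the Revised
    DMC (RDMC), whose channel weights shift exponentially from the automatic
    to the controlled route. Defective first-passage-time densities are
    computed by Crank-Nicolson solution of the Kolmogorov forward equation
    between absorbing boundaries and convolved with a uniform non-decision
    time. The package provides maximum-likelihood fitting by bounded
    differential evolution, AIC/BIC model comparison, distributional
    descriptives (RT quantiles, delta functions, conditional accuracy
    functions), synthetic trial generation by inverse-transform sampling,
    and a full parameter-recovery study harness with blind and
    near-optimal-start protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
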