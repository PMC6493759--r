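Package: gllvmlite
Title: Approximate Likelihood Estimation for Generalized Linear Latent
    Variable Models
Version: 0.1.0
Authors@R:
    person("gllvmlite", "developers", email = "gllvmlite@example.org",
           role = c("aut", "cre"))
Description: Likelihood-based estimation of generalized linear latent
    variable models (GLLVMs) for multivariate abundance data (species
    counts or presence-absence records collected at a set of sites).
    Two closed-form approximations to the intractable marginal
    likelihood are provided, a variational lower bound and the Laplace
    approximation, both maximized with analytic gradients.  The package
    also implements a data-driven starting-value algorithm based on
    Dunn-Smyth residuals and factor analysis, Wald inference from the
    approximate information matrix, latent-variable prediction,
    model-based ordination utilities (Procrustes error, variation
    explained), a simulator, and a small simulation-study harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    numDeriv,
    vegan,
    statmod,
    mvtnorm
Config/testthat/edition: 3
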