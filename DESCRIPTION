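Package: pincdm
Title: Probabilistic-Input Noisy Conjunctive Cognitive Diagnosis Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian estimation of conjunctive cognitive diagnosis models in
    which attribute mastery is either binary (DINA, HO-DINA) or probabilistic
    (PINC, HO-PINC), with a single higher-order latent trait optionally
    linking the attributes. Provides a Metropolis-within-Gibbs sampler with
    burn-in adaptation, Brooks-Gelman convergence diagnostics, model-fit
    indices (DIC with effective parameters var(D)/2, and -2LCPO at test and
    item level via the conditional predictive ordinate), a data simulator for
    all four model variants, and a parameter-recovery study runner with
    convergence-gated dataset replacement and RMSE/correlation scoring.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
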