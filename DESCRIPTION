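Package: phyloprev
Title: Phylogenetic Comparative Methods for Species-Level Disease Prevalence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the evolution of species-level disease
    prevalence on phylogenies. Provides maximum-likelihood fitting of nine
    models of continuous trait evolution (Brownian motion,
    Ornstein-Uhlenbeck, early burst, Pagel's lambda, delta and kappa, rate
    trend, mean trend, white noise), AIC-based hierarchical model selection
    across clades, measurement-error phylogenetic generalized least squares
    under a chosen or automatically selected model, binomial regression with
    a phylogenetic working correlation (generalized estimating equations),
    maximum-likelihood ancestral state reconstruction with confidence
    intervals, and a Monte-Carlo harness comparing false-positive and
    false-negative rates of phylogenetic regression methods on simulated
    prevalence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    nlme,
    phytools,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
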