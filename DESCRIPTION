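Package: fitqg
Title: Quantitative Genetics of Fitness in Pedigreed Wild Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian animal models for non-Gaussian fitness data in wild
    pedigreed populations. Fits zero-inflated Poisson, Poisson and binary
    (logit) animal models by Markov chain Monte Carlo with
    parameter-expanded priors and pedigree-structured additive genetic
    effects, converts latent-scale variance components to data-scale
    population means, phenotypic and additive genetic variances,
    heritabilities and evolvabilities, and runs simulation-based power
    analyses for detecting small additive genetic variances in fitness.
    Includes pedigree utilities (validation, pruning to phenotyped
    individuals, relatedness summaries, the additive relationship matrix and
    its sparse inverse) and a synthetic-data module that emulates the
    pedigree structure and zero-inflated fitness distributions of a
    long-term seabird study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Matrix,
    coda,
    statmod,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
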