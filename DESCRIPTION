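Package: colonyQG
Title: Quantitative Genetics of the Social Environment in Breeding Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative-genetic analysis of age-dependent social
    environments in pedigreed breeding colonies. Builds a neighbour-density
    trait from mapped nest coordinates, partitions age effects into between-
    and within-individual components, and fits Bayesian overdispersed-Poisson
    (Poisson-lognormal) animal models by Markov chain Monte Carlo, including
    random-regression models of individual and additive-genetic variation in
    ageing slopes (genotype-by-age interaction). Includes a synthetic colony
    generator with known ground truth for validation, pedigree utilities
    (pruning, additive relationship matrices), posterior summaries (modes,
    highest-posterior-density intervals, effective sample sizes), deviance
    information criterion comparison, and an end-to-end analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    coda,
    knitr
Config/testthat/edition: 3
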