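Package: lrcdorm
Title: Simulation and Inference for Label-Retaining Dormant Leukemia Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative machinery for studying rare dormant (label-retaining)
    subpopulations in patient-derived xenograft models of acute lymphoblastic
    leukemia. Provides a stochastic simulator of label-diluting, niche-limited
    leukemic growth with a reversible dormant compartment; CFSE bisection
    counting and label-retaining-cell (LRC) gating; exponential versus logistic
    growth model fitting and selection; single-hit Poisson limiting-dilution
    estimation of leukemia-initiating cell frequency with profile-likelihood
    confidence intervals; differential drug-effect statistics including
    relative drug effect, LRC enrichment and minimal-residual-disease calling;
    and derivation and comparison of dormancy gene signatures (rank-sum
    differential expression, hypergeometric overlap, sign concordance, and a
    permutation-based rank enrichment score).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
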