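Package: coalabc
Title: Approximate Bayesian Computation for Demographic Scenario Choice
    from mtDNA Haplotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coalescent-based approximate Bayesian computation (ABC) for
    inferring the order and timing of divergence among regional populations
    sampled at a single linked mitochondrial locus. Provides a structured
    coalescent simulator with population splits, admixture pulses and
    stepwise size changes; HKY+I+Gamma sequence evolution along simulated
    genealogies; a fixed 12-statistic summary (haplotype counts, segregating
    sites, mean pairwise differences, pairwise Hudson F_ST) plus descriptive
    diversity statistics with AMOVA-style Phi_ST permutation tests; reference
    table construction, rejection sampling, logistic-regression model choice
    with asymptotic confidence intervals, local-linear regression posterior
    adjustment on the logit scale, and posterior-predictive model checking;
    and a synthetic-data generator that emulates a three-population
    screwworm-fly study design with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    nnet,
    stats,
    utils,
    yaml,
    jsonlite,
    ape,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
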