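Package: levotap
Title: Levodopa Motor-Response Modelling and Parameter Estimation in
    Parkinson Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates levodopa plasma kinetics with a two-compartment
    oral-absorption model, links plasma concentration to a delayed brain
    effect site and a sigmoid-Emax (Hill) dopaminergic input, and feeds
    that input to a two-channel Go/NoGo basal-ganglia firing-rate network
    that produces alternate finger-tapping frequency. Provides automatic
    per-patient estimation of the three pharmacokinetic and six
    pharmacodynamic parameters by multi-restart Nelder-Mead minimisation
    of a bespoke cost function, clinical response metrics (latency,
    duration, stable versus fluctuating classification), exact rank-sum
    group comparison with Bonferroni correction, dopamine-gated Hebbian
    training experiments, and a synthetic-patient generator that emulates
    the clinical sampling protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
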