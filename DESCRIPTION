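Package: herdnet
Title: Agent-Based Simulation of Pastoral Herd Dynamics and Patron-Client Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic agent-based model of nomadic pastoral households
    sharing a common pasture. Household herds grow multiplicatively under a
    system-wide carrying capacity, suffer random environmental disasters, and
    form patron-client support networks in which wealthy households transfer
    animals to impoverished ones. The package provides a fast simulation
    engine together with a naive reference engine for cross-validation,
    dependent-variable metrics (Gini index of herd wealth, size and duration
    of the largest patron-client network), reproducible batch and
    parameter-sweep experiment runners, a capacity-shift experiment,
    standardized-coefficient multiple regression for sensitivity analysis,
    ggplot2 visualisations, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    generics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
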