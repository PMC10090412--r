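Package: sensgame
Title: Evolutionary Game Models of Migraine Persistence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying why a costly hypersensitivity phenotype
    (the migraineur) can persist at a stable frequency in a population.
    Builds the classic Hawk-Dove contest game from its scoring primitives
    and the migraineur/non-migraineur cooperation game from cost
    parameters, solves for mixed evolutionarily stable states, integrates
    deterministic replicator dynamics, simulates a finite-population Moran
    birth-death process, runs an agent-based model of the reciprocal
    altruism exchange (warning of predators versus rescue during attacks,
    with repeated interaction, recognition and memory as switchable
    conditions), and performs comparative-statics sweeps of the
    equilibrium phenotype frequency. Results are tidy tibbles with broom
    style tidy()/glance() methods and ggplot2 autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
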