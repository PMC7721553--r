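Package: preconbia
Title: Budget-Impact Modelling of Pre-Conception Lifestyle Interventions
    in Subfertility Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic cohort budget-impact model for pre-conception
    lifestyle intervention programs offered to subfertile couples undergoing
    assisted reproductive technology (IVF, ICSI, IUI). Converts published
    effect rates into annual changes in spontaneous pregnancies, treatment
    cycles and pregnancy complications, prices them into per-couple and
    population-level cost savings with least/central/most-favorable scenario
    bounds, and adds an optional Monte Carlo probabilistic sensitivity
    analysis. Ships a fully parameterised Netherlands 2016 model population,
    a cell-by-cell audit of recomputed against published table values, a
    seeded generator of synthetic parameter sets for property testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
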