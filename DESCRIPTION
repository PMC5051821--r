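Package: stemdiv
Title: Clade-Level Diversification Analysis from Dated Family Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing diversification on fossil-calibrated,
    family-level phylogenies whose tips are terminally unresolved clades
    with known species richness. Implements species-richness correction
    from taxonomic evaluation counts, stem-age net diversification
    estimation under bounded relative extinction, age-window regressions
    of log richness on clade age with nested-clade pruning and
    Benjamini-Hochberg correction, a permutation null for the
    rate-richness correlation, stepwise AICc birth-death rate-shift
    detection on trees with unresolved tips, and birth-death simulators
    for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
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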