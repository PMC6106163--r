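Package: apparency
Title: Plant Dominance and Leafminer Host Incidence with Phylogenetic
    Logistic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes plant importance values (relative density, frequency
    and size) from community plot surveys, area-weighted total importance
    values (TIV) and group importance values, ranks taxa into dominance
    groups and tabulates leaf-mining insect host ratios by rank group and
    plant attribute. Builds a dated local phylogeny by grafting a taxon
    list onto a family/genus megatree and interpolating node ages, and
    fits binary phylogenetic generalized linear mixed models (penalized
    quasi-likelihood), phylogenetic logistic regressions with an
    Ornstein-Uhlenbeck correlation parameter, and ordinary logistic
    regressions of leaf-mine presence on plant dominance. Includes a
    synthetic community-survey generator so the full pipeline is testable
    end to end.
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
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
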