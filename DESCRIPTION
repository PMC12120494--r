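Package: avinest
Title: Taxonomic and Functional Nestedness of Urban Bird Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the nestedness analysis of species-by-site community
    matrices, motivated by bird assemblages in urban parks. Computes binary
    NODF and weighted WNODF with row (species incidence) and column (site
    composition) components; tests them against four Monte-Carlo null models
    (proportional-proportional, fixed row/column totals, equiprobable, and
    fixed-fill placement); assesses passive sampling with Coleman's random
    placement model and a one-third rule; estimates abundance-based sample
    coverage and rarefaction/extrapolation curves for inventory completeness;
    and measures functional nestedness with treeNODF (shared branch length on
    a Gower/UPGMA trait dendrogram) decomposed into S.Fraction and topoNODF,
    with a row-permutation significance test. A synthetic community generator
    with a tunable nestedness dial supports power and type-I calibration
    studies, and a pipeline function orchestrates the full workflow into tidy
    report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
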