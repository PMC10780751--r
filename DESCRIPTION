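Package: metstab
Title: Stability Analysis for Multi-Environment Trials (AMMI, GGE, WAAS and Rank-Based Clustering)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing balanced multi-environment trials (METs) laid
    out as randomized complete block designs. Implements the joint analysis of
    variance with genotype-by-environment interaction (GEI) decomposition, the
    additive main effects and multiplicative interaction (AMMI) model with
    Gollob F-tests and AMMI1/AMMI2 biplot coordinates, GGE biplot geometry
    (which-won-where polygon sectors, mean-versus-stability projections and
    ideal-genotype ranking), the weighted average of absolute scores (WAAS)
    and a panel of parametric and nonparametric stability statistics
    (Wricke ecovalence, Shukla stability variance, Eberhart-Russell joint
    regression, Annicchiarico reliability, Lin-Binns superiority, Tai
    statistics, Huehn and Thennarasu rank statistics), Ward clustering of
    genotype rank profiles, and Spearman trait-yield correlation. A synthetic
    MET generator with a configurable variance partition and low-rank GEI
    supports testing and power studies without field data.
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
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
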