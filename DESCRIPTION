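Package: shapeconv
Title: Quantifying Evolutionary Convergence in 3D Landmark Shape Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for measuring evolutionary convergence in 3D geometric
    morphometric data and attributing it to ecological and behavioural
    variables. Implements Generalised Procrustes Analysis with optional
    mirroring, thin-plate-spline bending energy and damped semilandmark
    sliding, pairwise Procrustes distances with analogue/non-analogue
    pair-type contrasts and affiliation permutation tests, the Wheatsheaf
    index of convergence strength, ordinary and phylogenetic two-block
    partial least squares with hierarchical permutation tests, Blomberg's K,
    adaptive-subspace removal, leave-k-out stability analysis, and a
    synthetic-study generator (labyrinth-like landmark templates, pure-birth
    trees, Brownian-motion shape evolution with planted convergent regimes)
    with known ground truth for every stage.
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
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
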