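Package: cyanogrowth
Title: Proteome Allocation, Growth Physiology and Quantitative Proteomics of
    Cyanobacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative analysis of phototrophic growth in
    cyanobacteria. Implements a coarse-grained proteome-allocation model of
    light-limited, light-saturated and photoinhibited growth solved by
    steady-state growth-rate maximization, with grid-search maximum-likelihood
    fitting of the photosynthetic-unit parameters to measured light-growth
    curves. Also provides the accompanying physiology calculus (turbidostat
    growth rates, gas-exchange rates and photosynthetic ratios, morphology and
    per-cell conversions), a label-free proteomics statistics pipeline
    (filtering, pairwise Kruskal-Wallis growth-dependence classification,
    k-means profile clustering with elbow selection, GO-slim Fisher
    enrichment), iBAQ-based absolute protein and complex quantification, and
    synthetic-data generators with planted ground truth for every input the
    pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
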