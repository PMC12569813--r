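Package: standopt
Title: Stand Structure Indexes and Multi-Agent Optimization for Circular Forest Plots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and optimizing the spatial structure of
    circular forest plots. Computes per-tree spatial structure indexes
    (uniform angle index, neighborhood comparison, complete mingling,
    stratification index, crown competition index) over Voronoi spatial
    structure units with buffer-zone edge correction, evaluates a
    multiplicative-divisive stand-structure objective under silvicultural
    constraints, and couples selective harvesting with Delaunay-gap
    replanting through a two-agent deep Q-learning optimizer. An
    individual-tree prediction module advances stands in five-year cycles
    so that optimization can be iterated toward an ideal structural state.
    Includes a seeded synthetic-stand generator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deldir,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
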