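Package: pearlscape
Title: Seascape Population Genomics and Larval Dispersal Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated toolkit for range-wide seascape genomics of
    broadcast-spawning marine invertebrates, motivated by the black-lip
    pearl oyster. Provides a DArT-style SNP quality-control cascade with a
    full accounting ledger, population-genetic diversity and structure
    statistics (Weir-Cockerham FST, Nei's standard genetic distance,
    hierarchical AMOVA, Mantel isolation-by-distance tests, LD-method
    effective population size, individual heterozygosity metrics),
    simulation-based FST-outlier detection with false-discovery-rate
    control, mutual k-nearest-neighbour population networks and
    neighbour-joining trees, and a Lagrangian larval-dispersal simulator
    driven by gridded daily surface currents with random-walk eddy
    diffusivity. Synthetic-data generators for hierarchical island-model
    genotypes and analytic current fields make every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
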