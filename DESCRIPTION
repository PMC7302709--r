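Package: pearldrift
Title: Lagrangian Larval Dispersal Simulation and Spat Recruitment Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Biophysical modelling toolkit for broadcast-spawning marine
    invertebrate larvae. Simulates passive larval transport as Lagrangian
    particles advected by gridded daily surface currents with a random-walk
    horizontal eddy diffusivity, seeds particles uniformly over reef habitat
    polygons, accumulates cumulative particle-visit counts on the forcing
    grid to map putative settlement areas, and compares simulated site
    counts against observed spat-collector recruitment with correlation,
    rank-sum and per-site tests. Includes analytic synthetic current fields
    (constant, zonal jet, double gyre), island seed-polygon generators and
    an overdispersed spat-count simulator for fully reproducible desk-scale
    scenarios.
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
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
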