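Package: radsim
Title: Individual-Based Simulation of Genetic-Distance Speciation and Radiations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the evolution of a sexual, zero-sum population whose
    state is the matrix of pairwise genetic similarities, with assortative
    mating restricted to sufficiently similar partners and optional negative
    frequency-dependent selection (rare types, i.e. individuals with few
    compatible partners, mate more often). Species are connected components of
    the compatibility graph; speciation events are detected and classified as
    fission (a death severs the sole genetic pathway within a species) or
    mutation-induced (a newborn is incompatible with everyone). Provides
    analytic feasibility checks, radiation summaries (species-through-time
    curves, speciation-rate trends, abundance symmetry, rank-abundance and
    Shannon diversity), a quasi-likelihood grid-search fit of simulated
    speciation-time series to observed species-through-time data with
    percentile confidence bands, synthetic fixture generation, and
    tidyverse-style tabular outputs with ggplot2 plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    readr,
    yaml,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    ape,
    optparse
Config/testthat/edition: 3
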