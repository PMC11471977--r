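Package: amazodex
Title: Curation and Diversity Analysis of Amazonian Amphibian Occurrence Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for curating multi-source species
    occurrence records and analysing amphibian diversity across the Amazon
    biome. Implements three sequential validation filters (taxonomic
    refinement with open-nomenclature detection and synonym resolution,
    geographic coordinate checks with a 20 km precision rule, and
    biogeographic containment with distribution-code vetting), sub-basin
    regionalization from a nested drainage hierarchy, equal-area 50 x 50 km
    gridding, incidence-based diversity statistics (richness, endemism,
    Jaccard similarity with UPGMA clustering, species accumulation curves,
    second-order jackknife richness estimation, Poisson regression of
    richness on basin area), and summary reporting of conservation status,
    temporal trends, and data-source complementarity. Ships a synthetic-data
    generator with a known truth ledger so every stage is testable without
    network downloads.
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
    withr,
    yaml
Suggests:
    ape,
    geosphere,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
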