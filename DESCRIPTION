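Package: microhorizon
Title: Horizon Plots for Longitudinal Microbiome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds horizon plots from longitudinal compositional microbiome
    data. Reads OTU/ASV tables (counts or relative abundance) together with
    sample metadata and an optional taxonomy table, filters taxa by prevalence
    and mean relative abundance, regularizes irregularly sampled time series by
    linear interpolation with gap breaks, folds each series into signed,
    clamped horizon bands around a per-taxon origin, and renders the result as
    a faceted vector or raster figure. Includes a seeded synthetic-data
    generator so the whole pipeline is testable without external datasets, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    grDevices,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite,
    xml2
Config/testthat/edition: 3
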