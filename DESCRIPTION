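Package: psfBEF
Title: Plant-Soil Feedbacks and Biodiversity-Productivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing factorial plant-soil feedback (PSF) field
    experiments and their consequences for biodiversity-productivity
    relationships. Computes species-by-soil PSF index values with bootstrap
    confidence intervals, simulates discrete logistic plant-community growth
    with and without soil-conditioning feedbacks, partitions net biodiversity
    effects into complementarity and selection components (Loreau-Hector
    additive partitioning), and fits richness-biomass and predicted-versus-
    observed regressions. Includes a synthetic-data generator that emulates a
    16-species factorial soil-training design so the full pipeline can be
    exercised and tested without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
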