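Package: holofun
Title: Per-Capita and Reef-Level Ecosystem Function Estimation for Sea
    Cucumbers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-capita ecosystem-function rates of sympatric
    sea cucumber species (ammonium excretion from sealed-bag incubations,
    sediment processing from in situ fecal pellet observations) and
    upscales them by bootstrap resampling to per-unit-seagrass-area
    reef-level contributions. Includes reef-survey geometry and density
    computation, a pooled length-to-wet-weight allometry, a centred-weight
    by species excretion model, species-contrast statistics at individual
    and reef level, and a seeded synthetic survey generator calibrated to
    published summary statistics so the full pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
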