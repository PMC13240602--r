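Package: standcycle
Title: Disturbance-Driven Forest Carbon-Cycle Simulation and Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reduced-complexity, mass-conserving annual carbon-pool model for
    disturbance-driven forest landscapes. Simulates gross primary productivity,
    autotrophic and heterotrophic respiration, stand-replacing wildfire with
    tissue-specific combustion and litter partitioning, wood harvest with
    decaying product pools, CO2-fertilization downregulation, and dynamic
    age-class tiling with a capped tile count. Includes seeded generators for
    synthetic climate forcing, a four-member disturbance-scenario ensemble, and
    pseudo-tower observations; factual/counterfactual site evaluation via the
    change in mean absolute error; factorial attribution of net biome
    productivity to climate, CO2 and disturbance channels with closure
    auditing; and national aggregation with rolling-window trend tests and
    source-sink transition estimation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
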