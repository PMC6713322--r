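Package: sgrnet
Title: Reservoir-Computing Estimation of Fish Specific Growth Rate from
    Digestive Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the weight specific growth rate (SGR, percent per day)
    of individual fish from body weight, the pyloric-caecal trypsin to
    chymotrypsin activity ratio (T/C ratio, a digestive-efficiency index) and
    the condition factor (CF), using an echo state network: a fixed sparse
    random recurrent reservoir with a linear readout trained online by
    recursive least squares with a forgetting factor. Includes min-max
    normalization to [-1, 1], seven-way input-ablation studies, 85/15
    train/test evaluation with mean-squared-error reporting, cross-population
    application of trained models with linear output rescaling to real units,
    a seeded synthetic fish-data generator for juvenile to adult stage
    presets, CSV ingestion, bit-exact text model persistence, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
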