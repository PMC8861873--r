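Package: lbpcea
Title: Cost-Utility Markov Model for Digital Therapeutic Care in Low Back Pain
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time Markov cohort model for the cost-utility analysis of a
    digital therapeutic care (DTC) app versus treatment as usual (face-to-face
    physiotherapy) for non-specific low back pain in the German statutory health
    insurance setting. Implements a seven-state transition model with tunnel
    treatment states, life-table (half-cycle) correction, annual discounting,
    incremental cost-effectiveness ratios with dominance classification, one-way
    deterministic sensitivity analysis with tornado ordering, a scenario suite
    over alternative horizons and attrition rates, and an individual-level
    microsimulation that serves as an independent Monte-Carlo oracle for the
    cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
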