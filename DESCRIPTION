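Package: pfindex
Title: Fuzzy Evaluation of Individual Physical Fitness Indices from Small Samples
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates one-sided, capability-style physical fitness indices
    (cardiorespiratory endurance, muscular endurance, muscular power,
    flexibility) from small repeated-measurement samples, builds
    half-triangular fuzzy numbers from their chi-square/normal upper
    confidence limits, and performs a confidence-limit-based fuzzy
    hypothesis test via the dR/dT ratio with a tri-state decision
    (improve / re-evaluate / maintain).  Includes a seedable Monte-Carlo
    module that validates the coverage of the upper confidence limit and
    maps the operating characteristics of the fuzzy test, plus CSV/YAML
    input, report rendering and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    parallel,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
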