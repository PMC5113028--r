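Package: havglove
Title: Tool-Specific Effectiveness of Vibration-Reducing Gloves at the Fingers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Transfer-function assessment of vibration-reducing (VR) gloves for
    hand-transmitted vibration at the fingers. Builds one-third octave band
    grids and the ISO 5349-1 hand-arm frequency weighting (Wh), synthesizes
    glove-finger transmissibility spectra from point-level laser-vibrometer
    style measurements, ingests tri-axial tool vibration spectra, computes
    tool-specific weighted and unweighted glove transmissibility values and
    percent vibration reductions, and classifies glove-tool matches. Includes
    a seeded synthetic-data generator (single-resonance base-excitation glove
    curves, peaked tool spectra) so the full pipeline can be exercised and
    validated without access to laboratory measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    tools,
    stats,
    withr,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
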