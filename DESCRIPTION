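Package: cloudpoint
Title: Image-Based Detection of Protein Cloud-Point and Ice-Nucleation
    Temperatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for determining apparent protein cloud-point temperatures
    (liquid-liquid phase separation) and ice-nucleation temperatures from
    time-lapse images of microtiter-plate wells on a cooling ramp. Extracts
    per-frame turbidity traces (total intensity difference, total white
    pixels under fixed and data-dependent white levels, mean color levels),
    detects clouding and freezing events on smoothed traces, and aggregates
    technical replicates with Tukey-fence outlier rejection and median/MAD
    summaries. Includes a seeded synthetic well-plate generator with a
    first-order device-versus-sample thermal-lag model, so the systematic
    depression of apparent cloud points with cooling rate and sample volume
    can be reproduced and every pipeline stage validated against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
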