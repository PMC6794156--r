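Package: ffrplan
Title: Virtual PCI Planning and Pressure-Wire Pullback Simulation for
    Serially Stenosed Coronary Vessels
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Reduced-order hemodynamic modelling of serially diseased
    coronary arteries. Represents a vessel as a sampled lumen radius
    profile, detects and quantifies stenoses, solves steady hyperemic
    pressure and fractional flow reserve (FFR) profiles with a viscous
    plus expansion-loss pressure-drop law, calibrates a flow-dependent
    epicardial resistance model (R = R_in + R_sl * Q) per segment against
    a fine-grid solver, and virtually stents chosen lesions by lumen
    idealization to predict the residual FFR contribution of the lesions
    left behind. Includes an in-silico pressure-wire pullback, per-lesion
    apparent and isolated ("true") FFR gradients, method-agreement
    statistics (paired t, Pearson, Bland-Altman, TOST equivalence), and a
    seeded synthetic cohort generator for end-to-end experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
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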