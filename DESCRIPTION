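Package: osteoforce
Title: Energy Dissipation from AFM Force Spectroscopy and Paired Bone
    Fracture-Toughness Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantifying energy dissipation of adhesive
    protein networks (such as osteopontin films) from atomic force microscopy
    force-spectroscopy retraction curves, together with the paired-design
    biostatistics of an ex-vivo bone cohort: cantilever calibration (stiff-surface
    optical lever sensitivity and thermal-noise spring constant), per-pull
    maximum adhesion force, pulling length and dissipated energy, condition
    summaries normalized to reference environments, notched-femur maximum-load
    fracture toughness with specimen validity filtering, global matrix
    phosphorylation levels, and contralateral-limb paired deltas. A synthetic
    data module generates force-curve cycles, calibration inputs and paired
    cohorts with known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
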