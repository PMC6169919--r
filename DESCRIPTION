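Package: femurtough
Title: Fracture Toughness, Morphometry and Matrix Biochemistry of Notched
    Mouse Femurs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for notched-femur three-point-bend tests in
    small-animal radiotherapy studies. Converts synchronized load-displacement
    and crack-extension records into linear-elastic fracture toughness at
    crack initiation, peak load and instability (K_init, K_pl, K_inst) using a
    closed-form stress intensity solution for a circumferential through-wall
    crack in a cylinder loaded in bending, with plastic-zone-based validity
    diagnostics and sagittal fracture-angle measurement. Computes
    mid-diaphyseal cortical morphometry (areas, mean cortical thickness,
    principal second moments of area, tissue mineral density) from calibrated
    micro-CT density sections, quantifies advanced glycation end products and
    collagen from fluorescence plate readings, and provides the longitudinal
    statistical battery (per-time-point t tests, ANCOVA with treatment-by-time
    interaction, ANOVA with Tukey post-hoc tests, regressions, Cohen's d,
    percent change). A calibrated synthetic-data module generates every input
    with planted ground truth so the whole chain is testable without animal
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    car,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
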