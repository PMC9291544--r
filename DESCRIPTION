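Package: coralMHW
Title: Projecting Coral Responses to Marine Heatwaves Under Ocean
    Acidification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to project the performance and survival of reef-building
    corals under intensifying marine heatwaves and ocean acidification.
    Computes experiment-level effect sizes (Arrhenius activation energy in eV
    for warming contrasts, log response ratios per 100 uatm pCO2 for carbonate
    chemistry contrasts), classifies full-factorial warming x CO2 experiments
    as additive, synergistic or antagonistic, pools effect sizes with
    multilevel random-effects meta-analysis (crossed study and genus
    intercepts, REML via 'metafor'), back-transforms pooled effects to
    percent-change projections under RCP warming and CO2 scenarios including
    a threshold-sensitivity search, and detects marine heatwaves in daily sea
    surface temperature series by percentile exceedance with annual statistics
    and multi-model envelopes. Includes synthetic-data generators with known
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    metafor,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
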