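Package: sprscreen
Title: Surface Plasmon Resonance Screening Pipeline for Direct-Binder Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of label-free surface plasmon resonance (SPR)
    small-molecule screens against immobilized protein targets. Implements the 1:1
    Langmuir interaction model for sensorgram simulation and global kinetic fitting
    (ka, kd, KD, Rmax), steady-state affinity fitting, double-reference subtraction
    and DMSO solvent correction of multi-spot sensorgrams, a stoichiometry-aware
    primary-hit triage cascade based on theoretical Rmax and high/low-density surface
    comparison, reporter-assay secondary screening criteria, and confirmation-tier
    analytics (cellular thermal shift melt-curve quantification, four-parameter
    logistic dose-response fitting, selectivity indices, and group IC50 comparison).
    Includes seeded synthetic-data generators for every pipeline input so the whole
    screen is reproducible and testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    yaml
Config/testthat/edition: 3
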