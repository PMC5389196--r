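Package: nanoqspr
Title: Nano-QSPR Modelling of Halogenated Dioxin Adsorption on Fullerene C60
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative structure-property relationship (QSPR)
    modelling of the adsorption of brominated, chlorinated and mixed
    bromo/chloro dibenzo-p-dioxin congeners on the C60 fullerene surface.
    Enumerates all 1,701 symmetry-distinct H/Cl/Br substitution patterns of
    the dibenzo-p-dioxin skeleton, generates a synthetic quantum-chemistry
    style descriptor table with a configurable linear ground truth, selects
    representative calibration compounds with the Kennard-Stone algorithm,
    fits partial least squares (PLS) regression with genetic-algorithm
    descriptor selection, validates models internally (leave-one-out) and
    externally, and assesses the leverage-based applicability domain
    (Insubria plot data).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
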