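Package: sprkin
Title: Binding Kinetics of Lectin-Glycoconjugate Interactions from SPR and ELISA Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward simulation and global nonlinear fitting of surface plasmon
    resonance (SPR) sensorgrams under 1:1 Langmuir, heterogeneous-ligand,
    bivalent-analyte and heterogeneous-analyte kinetic models, with
    interspot/blank double referencing, AICc-based model comparison and
    error-propagated equilibrium dissociation constants (KD = kd/ka).
    Companion tools fit ELISA saturation and competitive-inhibition
    dose-response curves, quantify the cluster glycoside effect of multivalent
    neo-glycoproteins (relative potency and relative potency per glycan), and
    evaluate Linear Interaction Energy binding free energies from mean
    ligand-environment interaction energies. A seeded synthetic-data generator
    emulates multi-concentration sensorgram series with reference channels and
    ELISA dose-response curves for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
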