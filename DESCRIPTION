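Package: bacnav
Title: Patch-Clamp Analysis and Simulation for Bacterial Voltage-Gated Sodium Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-cell and single-channel voltage-clamp analysis for prokaryotic
    voltage-gated sodium (Nav) channels, together with a deterministic synthetic
    recording generator. Implements Goldman-Hodgkin-Katz (GHK) ion-selectivity
    inference from bi-ionic reversal potentials with extended Debye-Hueckel
    activity corrections, P/4 leak subtraction, Boltzmann activation and
    inactivation fits, single-exponential inactivation kinetics, Q10/Arrhenius
    temperature analysis, Hill dose-response fitting for channel block and
    bacterial growth inhibition, and channel presets emulating the NsvBa,
    NaChBac and NavBp channels of alkaliphilic Bacillus.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
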