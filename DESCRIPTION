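Package: tapdose
Title: Preclinical Dosimetry and Pharmacology for Lead-212 Targeted Alpha Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for preclinical evaluation of Pb-212-labeled
    receptor-targeting radiopharmaceuticals. Provides the Pb-212 decay-chain
    physics (Bateman ingrowth, per-decay emission energy accounting, decay
    correction), biodistribution analytics (percent injected dose per gram,
    specific-activity effects, radiochemical purity), MIRD-style internal
    dosimetry with RBE-weighted absorbed-dose coefficients, mouse-to-human
    projection by the relative-concentration method, activity limits and
    safety margins, one-site saturation-binding Kd estimation, Kaplan-Meier
    efficacy endpoints with termination-criteria evaluation, and seeded
    synthetic-data generators emulating the study designs so every pipeline
    stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    minpack.lm,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
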