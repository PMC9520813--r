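Package: caseonly
Title: Case-Only Estimation of Susceptibility-Exposure Interaction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation of multiplicative susceptibility-factor by
    environmental-exposure interaction from case-only, case-control and
    full cohort (cases plus non-cases) designs. Provides closed-form
    interaction contrast ratios on aggregated 2x4 count tables, the
    matching logistic-regression estimators on subject-level data, the
    five-step case-only workflow with an independence check and
    conditional correction, assumption diagnostics (rare-disease
    sensitivity, confounding interaction ratio and its bounds, design
    efficiency comparison), and a seeded synthetic-population simulator
    with controllable susceptibility-exposure association and
    interaction strength.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
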