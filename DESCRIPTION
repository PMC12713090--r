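Package: fluxscan
Title: Enforced-Objective Flux Scanning for Metabolic Engineering Target
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constraint-based analysis of genome-scale metabolic models
    aimed at secondary-metabolite overproduction. Reads and writes models
    (SBML Level 3 with FBC, or a minimal JSON dialect), grafts heterologous
    pathway modules (a spinosyn biosynthetic module and the
    non-carboxylative malonyl-CoA route), and runs a modified FSEOF scan:
    biomass is enforced at stepwise fractions of its maximum, target flux
    is maximized at each level, and parsimonious FBA selects the reported
    flux distribution. Reaction and gene scores (production-regime flux
    relative to pure-growth flux) classify overexpression and attenuation
    targets. Includes synthetic toy-model generators with planted ground
    truth and an independent brute-force scoring oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
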