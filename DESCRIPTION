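Package: sbmdea
Title: Slacks-Based DEA Efficiency and Malmquist Productivity for Balanced Panels
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data envelopment analysis for balanced input/output panels:
    non-oriented slacks-based measure (SBM) efficiency, super-efficiency SBM
    scoring that ranks efficient decision-making units above one, and the
    adjacent-period Malmquist total-factor-productivity index with its
    EFFCH/TECH/PECH/SECH decomposition. Includes a synthetic panel generator
    with a known Cobb-Douglas frontier for end-to-end validation, reporting
    helpers that build effectiveness counts and index summary tables, and a
    small command-line driver. All programs are solved exactly as linear
    programs via the Charnes-Cooper transformation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
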