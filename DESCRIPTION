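Package: adenomaRisk
Title: Molecular Risk Classification of Colorectal Adenomas and Nested
    Case-Control Analysis of Metachronous Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying whether chromosome-arm copy-number
    alterations in a baseline colorectal adenoma predict metachronous
    colorectal cancer. Provides a synthetic cohort and copy-number
    profile generator, arm-level event calling from binned log2-ratio
    profiles with cancer-associated-event (CAE) scoring, incidence
    density (risk-set) matching of controls to cases, conditional
    logistic regression for 1:M matched sets implemented from the
    conditional likelihood with Newton-Raphson fitting, Kaplan-Meier and
    log-rank analysis, time-window-stratified odds ratios, and power and
    sample-size arithmetic for matched case-control designs. An
    end-to-end pipeline driver reproduces the full study workflow from a
    single configuration file.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    survival,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
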