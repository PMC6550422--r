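Package: cepsbvalid
Title: Validation of Hospital Discharge Data Algorithms for Complicated
    Ectopic Pregnancy with Severe Bleeding
Version: 0.1.0
Authors@R:
    person("HDD", "Validation Team", email = "hdd-validation@example.org",
           role = c("aut", "cre"))
Description: Tools to build and validate hospital-discharge-database (HDD)
    detection algorithms for complicated ectopic pregnancy with severe
    bleeding (CEPSB), a maternal near-miss condition. Provides a chart-review
    gold-standard case definition, declarative ICD-10/CCAM code-set detection
    algorithms (including two built-ins), a data-driven algorithm derivation
    rule based on per-code screening with Fisher exact tests and a positive
    likelihood-ratio threshold, diagnostic validity statistics (sensitivity,
    specificity, LR+ with 95 percent confidence intervals), a coding-error
    audit against ideal coding, and a truth-labelled synthetic cohort
    generator with configurable coding-error injection for end-to-end
    testing when the original hospital records are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
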