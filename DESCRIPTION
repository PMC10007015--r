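Package: aaanlp
Title: Rule-Based Extraction of Abdominal Aortic Aneurysm Diagnoses from
    Radiology Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-based clinical natural language processing pipeline that
    reads free-text radiology reports, segments them into named sections,
    matches abdominal aortic aneurysm (AAA) concept mentions against a
    configurable lexicon, assigns each mention an assertion status (affirmed
    or negated) using ConText-style trigger phrases with pseudo-negation
    masking, and classifies each report as an AAA case or control. Includes
    aortic dimension extraction with unit normalization, an optional strict
    diameter criterion, a diagnostic-performance evaluation suite (sensitivity,
    positive predictive value, specificity, F1, accuracy, Cohen's kappa), and
    a synthetic radiology-report generator with exact gold labels so every
    pipeline stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
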