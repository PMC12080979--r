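Package: dkaudit
Title: Guideline-Adherence Audit and Feedback for Diabetic Ketoacidosis Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable audit-and-feedback pipeline for diabetic ketoacidosis
    (DKA) care in adults. From raw episode records (timestamped labs,
    insulin and fluid prescriptions, discharge coding) it ascertains DKA
    episodes against JBDS-IP diagnostic and resolution criteria, scores
    per-episode adherence to fixed-rate insulin infusion dosing, fluid
    replacement and hourly glucose/ketone monitoring, detects treatment
    complications (hypoglycaemia, hypo-/hyperkalaemia), aggregates
    per-hospital quarterly key performance indicators, compares first versus
    last audit quarters with Pearson chi-square tests, and renders anonymised
    per-hospital feedback reports against a pooled peer summary. A seeded
    synthetic multi-hospital cohort generator with a ground-truth table makes
    every stage testable without access to any clinical registry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
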