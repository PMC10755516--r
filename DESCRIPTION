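Package: rltdose
Title: Organ Dosimetry for Lutetium-177 Radioligand Therapy with
    Single-Time-Point Scaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Internal dosimetry pipeline for multi-cycle Lu-177 radioligand
    therapy. Fits cycle-1 organ time-activity curves, computes time-integrated
    activities, derives later-cycle activities from a single post-administration
    measurement by scaling the cycle-1 curve, converts time-integrated activity
    into absorbed organ doses through the MIRD schema (S-value matrix sum) with
    sphere-model lacrimal-gland self-dose and blood-based red-marrow dosimetry,
    and compares predicted with observed cumulative doses using paired Hotelling
    T-squared tests with Bonferroni adjustment. Includes noncompartmental blood
    pharmacokinetics and a calibrated synthetic-cohort generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
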