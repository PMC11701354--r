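Package: scstriage
Title: Two-Stage Triage Evaluation for Spinal Cord Stimulation Referral
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A configurable indicator rule engine for two-stage triage of
    chronic low-back-and-leg-pain patients towards spinal cord stimulation
    (SCS) consultation, together with the full evaluation battery used to
    assess such a clinical decision rule: diagnostic accuracy against a
    reference referral decision (sensitivity, specificity, predictive values
    with binomial confidence intervals), inter- and intra-rater reliability
    (Cohen's and Fleiss' kappa, specific agreement), and System Usability
    Scale scoring with item-level benchmarks. Includes a seeded synthetic
    generator for patient cohorts, latent-class rater calls, and Likert
    usability responses, so every evaluation step is testable end to end
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
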