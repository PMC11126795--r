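Package: radcoder
Title: Automated ICD-10 Coding of Radiology Report Impressions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maps the Impression section of neuroimaging reports to ranked
    ICD-10-CM diagnosis codes with a contextual bag-of-words matcher:
    section extraction, line and phrase segmentation, normalization with
    clinical synonyms, pertinent-negative (negation) polarity, and an
    inverse-document-frequency weighted match score conditioned on exam
    body region. Includes the companion validation framework: unanimity
    ground truth from multi-reviewer annotations, threshold-based
    confusion classification, sensitivity/specificity/F2 grids over code
    lengths and rank cutoffs, inter-rater reliability statistics (Cohen
    and Fleiss kappa, Krippendorff alpha), and a seeded synthetic corpus
    and reviewer-panel generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
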