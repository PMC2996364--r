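Package: ccqagree
Title: Individual-Level Agreement Analysis for the Clinical COPD
    Questionnaire
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scoring and individual-patient agreement analysis for the
    Clinical COPD Questionnaire (CCQ), a 10-item, 7-point Likert health
    status instrument with symptoms, mental state and functional state
    domains.  Implements Lin's concordance correlation coefficient with
    its precision/accuracy decomposition and one-sided confidence
    limits, the Total Deviation Index, the Coverage Probability at the
    minimal clinically important difference, the two-way
    absolute-agreement single-rater intraclass correlation coefficient,
    and Bland-Altman quantities; generates and verifies balanced
    randomized assignments of patient interviews to reviewing
    clinicians; orchestrates the three-way patient / treating-clinician
    / reviewer-mean comparison as a reproducible pipeline; and simulates
    synthetic rater studies with analytically known population
    agreement for validation of every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
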