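Package: idoct
Title: Cognitive-Motor Decomposition of Trial-Level Digital Task Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Separates cognitive ability from hand-motor response delay in
    trial-level accuracy and reaction-time data from self-administered
    digital cognitive tasks. Implements an iterative decomposition that
    calibrates condition-level trial difficulty on a normative cohort,
    splits each reaction time into a cognitive answer time and a
    non-cognitive response delay time, and scores each test session with a
    difficulty- and speed-weighted Cognitive Index. Also provides an
    expectation-maximisation principal component analysis tolerant of
    missing entries for extracting a global cognition factor, longitudinal
    mixed-effects confound and criterion-validity analyses with
    Yeo-Johnson transformed outcomes and Benjamini-Hochberg false
    discovery control, permutation-tested canonical correlation analysis
    against imaging burden measures, and a synthetic stroke-cohort
    generator so the whole analysis can be validated end to end against
    known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    lme4,
    lmerTest,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
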