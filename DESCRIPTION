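Package: ctgaudit
Title: Metadata Quality Auditing for Clinical-Trial Registry Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Audits clinical-trial registration records in the
    ClinicalTrials.gov public-XML dialect for metadata quality: validates
    simple-typed fields (Boolean, integer, date, age) against their
    grammars, checks enumerated fields against the data dictionary's
    permitted value sets, audits interventional records for the FDAAA801
    required fields with conditional-requirement and Final Rule era logic,
    classifies eligibility-criteria text blocks into format classes and
    parses conformant blocks, and measures exact-match coverage of
    condition and intervention values against terminology lexicons such as
    MeSH. Includes a seeded synthetic-corpus generator with controlled
    defect injection so every audit stage is testable without the live
    registry.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
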