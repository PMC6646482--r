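Package: lesionext
Title: Extraction of Lesion Measurements and Their Descriptors from
    Radiology Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid rule-based and statistical pipeline that detects lesion
    size measurements in narrative radiology reports (CT, MR, mammography) and
    links each measurement to seven descriptors: temporality (current versus
    prior), anatomical entity, imaging observation, RadLex-style descriptor,
    image number, series number, and organ segment.  Report sectioning,
    measurement and temporality tagging, and scan-reference tagging are
    regular-expression grammars; entity tagging is either a dictionary
    baseline or a linear-chain conditional random field trained on
    token-level features.  Each measurement is emitted as one structured
    frame.  Includes a full/partial/no-match evaluation scheme with
    per-descriptor precision, recall and F scores, and a seeded synthetic
    report generator with paired gold annotations so the whole system can be
    trained and evaluated without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
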