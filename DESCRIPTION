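Package: dfid
Title: Identification and Normalization of Drug Dosage Forms in Drug Monographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-based pipeline that identifies the dosage forms of a drug
    (oral tablet, ophthalmic solution, ...) from the free text of consumer-level
    drug monographs and normalizes them to standardized dosage-form concepts
    organized in a hand-encoded hierarchy of dotted tree numbers. Includes
    monograph XML reading and writing, title segmentation into ingredient and
    route, pattern-based extraction of dosage-form evidence sentences, lay-route
    translation rules, stem-bag concept matching with a most-specific filter,
    silver-standard construction from brand names via branded-drug records,
    per-monograph and macro-averaged precision/recall/F evaluation, and a
    seeded synthetic-corpus generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
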