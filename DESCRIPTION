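Package: clinade
Title: Rule-Based Detection and Context Classification of Adverse Drug
    Event Mentions in Clinical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A rule-based pipeline for locating mentions of adverse drug
    events (ADEs) in free-text clinical notes and classifying each mention
    as a positive or a negative occurrence.  Documents are segmented into
    sentences and delimiter-bounded clauses; ADE terms from a bundled,
    user-extensible dictionary are located within clauses; a clause-scoped
    trigger-term engine in the style of the ConText/NegEx family assigns
    negation, experiencer, temporality and categorical value to every
    mention; and a catalogue of retention and removal rules corrects
    systematic misclassifications (negated drug administration, warnings
    and monitoring, questionnaires, organisation names and addresses).
    Includes an evaluation harness (precision, sensitivity, specificity,
    accuracy, F-measure against gold-standard annotations), JSONL and BRAT
    standoff writers, and a seeded synthetic clinical-note generator so
    the whole pipeline can be exercised without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    stringi,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
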