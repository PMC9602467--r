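Package: speechaug
Title: Stopword-Aware Text Augmentation for Imbalanced Speech-Transcript
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building class-balanced training sets from small,
    imbalanced corpora of transcribed speech, aimed at screening older adults
    for mild cognitive impairment from short task-elicited monologues.
    Implements transcript cleansing, the four Easy Data Augmentation
    operators (synonym replacement, random insertion, random swap, random
    deletion) with stopword protection, per-class augmentation multipliers,
    leakage-aware train/validation/test splitting with an explicit leakage
    audit, a pluggable classifier harness with grid search and early
    stopping, and weighted-F1 plus per-task evaluation reports. A synthetic
    corpus generator with configurable group-dependent lexical effects
    (pronoun rate, lexical diversity, event coverage) makes every stage
    testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
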