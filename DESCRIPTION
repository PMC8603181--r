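Package: solitairebm
Title: Digital Biomarkers of Cognitive Performance from Klondike Solitaire Gameplay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for deriving digital biomarkers of cognitive
    performance from Klondike Solitaire gameplay telemetry. Provides a
    deterministic rules engine (dealing, legality, legal-move enumeration,
    scoring, undo), a JSON Lines event-log format with a replay that
    classifies every gesture, extraction of 23 named biomarkers across six
    categories, two synthetic-data generators (an agent-based player with a
    tunable cognitive profile, and a model-based generator that draws
    biomarker tables from a generalized linear mixed model), expert-rating
    consensus analysis via two-way consistency intraclass correlation, and a
    group-difference analysis with crossed-random-effects mixed models,
    likelihood-ratio tests and marginal/conditional R-squared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
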