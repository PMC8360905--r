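Package: sutility
Title: Scalar Utility Theory Models of Two-Dimensional Reward Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how foragers evaluate rewards that vary in
    two dimensions (volume and probability). Implements six stochastic
    decision rules built on scalar utility theory (integrative,
    winner-takes-all, randomly non-compensatory, and lexicographic rules),
    a virtual-mouse choice simulator with closed-form choice probabilities
    for cross-checking, a synthetic nose-poke event-log generator that
    emulates automated home-cage sessions, discrimination-performance
    analysis with configurable acquisition cut-offs, bootstrap two
    one-sided tests (TOST) equivalence statistics with a four-outcome
    classification, per-mouse background-dimension regressions, and a
    grid-search calibration and out-of-sample RMSE ranking of the decision
    models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
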