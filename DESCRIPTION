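Package: pacstrat
Title: Compositional Strategy Analysis for Pac-Man-Style Foraging Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic, seedable simulator of a monkey-adapted Pac-Man
    foraging task together with the analysis pipeline that decomposes play
    into six basis strategies (local graze, global forage, two ghost-evasion
    strategies, ghost approach, and energizer seeking). Per-step strategy
    utilities are combined through a softmax mixture whose weights are
    estimated by a two-pass maximum-likelihood procedure with exact
    change-point segmentation; the fitted weights drive strategy labeling,
    game-context summaries, and compound-strategy event detection (planned
    attacks, accidental consumptions, suicides, failed evasions). Synthetic
    softmax agents with known piecewise-constant weight schedules provide
    ground truth for parameter-recovery validation, and a linear
    approximate reinforcement-learning model serves as a flat baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
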