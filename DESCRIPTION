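Package: huememory
Title: Simulation and Analysis of Color Constancy and Short-Term Color Memory
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study the interaction of color constancy and
    short-term color memory in two-alternative forced-choice (2AFC) hue
    judgments. Provides a quantitative Bayesian observer that generates
    binary "which appears bluer" responses under context (background
    color) and memory (retention delay) manipulations; a two-phase
    experiment engine that reproduces an interleaved weighted up-down
    staircase phase followed by a method-of-constant-stimuli phase in a
    2x2 factorial design (symmetric/asymmetric backgrounds crossed with
    simultaneous/delayed presentation); maximum-likelihood fitting of
    cumulative-normal psychometric functions with extraction of points
    of subjective equality, discrimination thresholds, and
    baseline-subtracted appearance biases; and an independence analysis
    that predicts joint constancy-and-memory biases from the pure
    effects by interpolation and quantifies departures with a bounded
    non-additivity index, together with supporting statistics
    (central-tendency slope, one-tailed sign tests, and bias-threshold
    correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    ggplot2
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
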