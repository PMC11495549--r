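Package: soycdrisk
Title: Soil-to-Soybean Cadmium Transfer and Probabilistic Dietary Health Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models cadmium (Cd) accumulation in soybean grain from paired
    soil Cd and soil pH observations in high-geological-background farmland,
    and assesses the resulting dietary health risk for adults. Provides a
    calibrated synthetic-cohort generator (Gaussian copula over
    moment-matched truncated-normal marginals), bioconcentration-factor and
    multiple-linear-regression accumulation models, a small sigmoid
    feed-forward neural-network predictor, deterministic average-daily-dose /
    hazard-quotient / carcinogenic-risk computation with regulatory
    classification, Monte-Carlo probabilistic risk with bootstrap percentile
    intervals, and mitigation-scenario analyses (maximum safe intake at a
    target cancer-risk percentile; uniform soil-pH increase propagated
    through the neural network).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    fitdistrplus,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
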