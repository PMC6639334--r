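Package: gainloss
Title: Gain-Loss Asymmetry in Risky Lottery Choice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing binary choices between two-outcome token
    lotteries in gain and loss domains, as used in primate risky-choice
    experiments. Implements a prospect-theory-style decision model
    (power utility with domain-specific risk attitude, Prelec probability
    weighting, and a monotone stochastic choice rule expressed through the
    risk-attitude indifference point), binomial maximum-likelihood fitting
    with chronological chunked cross-validation, the accompanying
    descriptive and inferential analyses (certainty-risk contrast,
    stochastic-dominance performance, expected-value-difference sigmoid,
    Mann-Whitney gain-versus-loss parameter contrasts, temporal trend
    regression), and a synthetic-agent trial generator emulating the
    token-gauge task design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
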