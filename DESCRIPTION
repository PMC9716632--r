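Package: woundcea
Title: Cost-Effectiveness Analysis of Wound Dressing Strategies
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-analytic cost-effectiveness analysis of two wound
    dressing strategies for chronic wounds from a payer perspective over a
    fixed time horizon. Implements a two-strategy, two-outcome decision tree
    with expected-cost rollback, incremental analysis (ICER and dominance
    classification), net monetary benefit, one-way deterministic sensitivity
    analysis with tornado ranking, and probabilistic sensitivity analysis by
    Monte-Carlo simulation with cost-effectiveness plane and acceptability
    curves. Scenario configurations are validated JSON documents; a built-in
    scenario compares hyaluronic-acid and silver-containing dressings under
    German statutory health insurance tariffs. A synthetic-scenario generator
    with closed-form expected-cost oracles supports fully self-contained
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
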