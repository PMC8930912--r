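Package: arhlce
Title: Early Health-Economic Model for Regenerative Therapeutics in
    Age-Related Hearing Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic Markov cohort model of the UK NHS hearing-care
    pathway for adults aged 50 and over with age-related hearing loss,
    built to value hypothetical regenerative hearing therapeutics before
    clinical data exist. Eleven annual-cycle health states (hearing-loss
    severity crossed with hearing-aid / cochlear-implant status, plus
    death) accrue discounted costs and quality-adjusted life years over a
    lifetime horizon. Provides probabilistic sensitivity analysis with
    Dirichlet, Beta and Gamma parameter uncertainty, headroom and scenario
    analyses reported as incremental net monetary benefit, and a
    value-based ceiling-price (threshold) search by bisection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
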