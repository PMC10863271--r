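Package: ntgcua
Title: Markov Cohort Cost-Utility Analysis of Normal-Tension Glaucoma
    Treatment Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic Markov cohort model for the cost-utility
    analysis of treating mild-stage normal-tension glaucoma (NTG).
    Runs annual-cycle cohort traces over mild, moderate, severe
    and dead states, accrues strategy-specific direct medical costs
    (medication, trabeculectomy with configurable uptake and failure,
    follow-up), discounts and half-cycle-corrects costs and
    quality-adjusted life years, and compares a positive (early
    intensive) strategy against traditional management via incremental
    cost-utility ratios judged against GDP-per-capita willingness-to-pay
    thresholds. Includes one-way (tornado) and probabilistic (Monte
    Carlo) sensitivity analysis, an individual-level microsimulation for
    cross-validation, and YAML/JSON parameter files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
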