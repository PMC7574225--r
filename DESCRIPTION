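Package: ceatree
Title: Decision-Tree Cost-Effectiveness Analysis for Sequential Therapy
    Pathways
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic modelling toolkit for two-strategy
    cost-effectiveness analyses over a short fixed horizon: decision-tree
    rollback to expected cost and effect size, incremental
    cost-effectiveness ratios (ICER) with dominance classification,
    one-way deterministic sensitivity analysis (parameter sweeps,
    break-even threshold search by bisection, tornado ranking), and
    seeded Monte-Carlo probabilistic sensitivity analysis with
    cost-effectiveness plane summaries, net monetary benefit and
    acceptability curves. Ships a calibrated model of conservative knee
    osteoarthritis management comparing sustained acoustic medicine
    against the standard-of-care therapy pathway over six months, plus
    generators for synthetic models with closed-form expected values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
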