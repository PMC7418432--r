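Package: trialcea
Title: Within-Trial Cost-Utility Analysis with Multiple Imputation and
    Bootstrap Uncertainty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for trial-based cost-utility analysis from a health-service
    perspective: micro-costing of a complex intervention from a line-item
    ledger with equipment annuitization, EQ-5D-3L utility scoring under a
    configurable value set, quality-adjusted life-years by the trapezoidal
    area-under-the-curve method with a death rule, deterministic item-level
    zero-filling plus arm-wise multiple imputation by chained equations with
    predictive mean matching, covariate adjustment via generalised linear
    models with recycled predictions (marginal standardization), and decision
    uncertainty via a non-parametric bootstrap of the full pipeline with
    incremental cost-effectiveness ratios, cost-effectiveness planes and
    acceptability curves. Includes a seeded synthetic two-arm trial generator
    emulating skewed service-use costs, small utility effects, missingness at
    random and attrition, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
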