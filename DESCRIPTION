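Package: ceadx
Title: Cost-Utility Modelling of Companion-Diagnostic Test-and-Treat Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost-utility modelling for companion-diagnostic
    testing followed by biomarker-guided therapy in advanced non-small cell
    lung cancer. Pools digitized Kaplan-Meier curves by trial sample size,
    extrapolates them with Weibull models fitted by log-log regression and by
    least squares on the survival scale, converts survival functions into
    time-varying monthly transition probabilities, runs a semi-Markov cohort
    model with per-line time-in-state clocks through first-line treatment,
    second-line treatment and best supportive care, and reports discounted
    costs, quality-adjusted life-years, incremental cost-effectiveness ratios
    with dominance labelling, scenario analyses and one-way (tornado)
    sensitivity analyses. Includes a synthetic Kaplan-Meier data generator
    with known ground truth for fully reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
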