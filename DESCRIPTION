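Package: her2cea
Title: Cost-Effectiveness of One-Year Adjuvant Trastuzumab for HER2+ Early Breast Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Markov cohort state-transition model evaluating one-year adjuvant
    trastuzumab combined with chemotherapy against chemotherapy alone for
    HER2-positive early-stage breast cancer, from a societal perspective in the
    Vietnamese setting. Provides the deterministic base case (lifetime costs,
    life years, quality-adjusted life years, incremental cost-effectiveness
    ratios), probabilistic sensitivity analysis with beta/gamma/log-normal
    parameter distributions, cost-effectiveness acceptability curves, expected
    value of perfect information, one-way (tornado) sensitivity analysis,
    threshold price search, and a weight-based vial-packing drug-cost
    calculator with a vial-sharing scenario. Includes a synthetic-data module
    (parametric Gompertz-Makeham life tables, closed-form toy models, parameter
    jittering) so the full analysis runs offline, an individual-level
    microsimulation oracle for the cohort engine, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
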