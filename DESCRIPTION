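Package: nbcea
Title: Net-Benefit Regression and Cost-Effectiveness Acceptability Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Cost-effectiveness analysis of two-arm interventions from
    household- or patient-level cost and effect data. Implements the
    net-benefit regression framework: per-record net monetary benefits at
    candidate willingness-to-pay ceiling ratios, least-squares estimation of
    the incremental net benefit (simple, stratified and covariate-adjusted),
    conversion of regression p-values into probabilities of
    cost-effectiveness, and cost-effectiveness acceptability curves with
    CEAC-based ICER and confidence-interval extraction. Includes the
    classical incremental cost-effectiveness ratio (ICER) analysis and
    cost-effectiveness plane classification it is compared against, and a
    calibrated synthetic-data generator emulating the Nouna (Burkina Faso)
    community-based health insurance household survey.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ggplot2,
    yaml,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
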