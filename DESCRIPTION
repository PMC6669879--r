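Package: ceatk
Title: Trial-Based Cost-Utility Analysis with Multiple Imputation and
    Bootstrap Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for economic evaluation alongside randomised trials:
    EQ-5D-3L tariff scoring and area-under-the-curve QALYs, micro-costing of
    group and individual psychotherapy sessions, unit-costing of health and
    social care use, medications and lost productivity, multiple imputation
    by chained equations with Rubin pooling, covariate-adjusted incremental
    costs and effects with a non-parametric bootstrap nested within the
    imputations, incremental cost-effectiveness ratios, cost-effectiveness
    planes and acceptability curves, and a set of pre-specified sensitivity
    scenarios. Includes a synthetic two-arm trial generator emulating the
    data structure these analyses assume, so the full pipeline is testable
    without access to confidential participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
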