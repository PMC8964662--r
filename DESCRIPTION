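Package: gracecea
Title: Generalized Risk-Adjusted Cost-Effectiveness Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Implements the generalized risk-adjusted cost-effectiveness
    (GRACE) framework for health technology assessment. Provides simplified
    hyperbolic absolute risk aversion (HARA) utility over health-related
    quality of life and exact recovery of relative risk-preference
    parameters (risk aversion, prudence, temperance); estimation of the
    elasticity of utility and relative risk aversion from happiness-survey
    data via a translog regression; severity- and disability-adjusted
    willingness-to-pay thresholds; conversion of trial-arm outcome moments
    into certainty-equivalence and substitution adjustments; and static
    plus multi-period net monetary benefit and cost-effectiveness decision
    rules, with JSON scenario configuration, CSV readers, synthetic data
    generators, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
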