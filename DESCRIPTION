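Package: reprometab
Title: Gonadotropin Pulsatility and Metabolomic Trend Analysis for
    Paired Diet-Intervention Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing frequent-sampling gonadotropin (LH/FSH)
    time series from paired crossover studies of dietary exposure:
    simulation of pulsatile hormone secretion with exponential
    elimination and assay noise, modified Santen-Bardin pulse detection
    with nadir-to-peak threshold criteria, endogenous and
    GnRH-stimulated area-under-the-curve response metrics, paired
    pre/post inference on the log scale with a normality-gated
    parametric/non-parametric switch, and a longitudinal metabolomics
    stage (repeated-measures ANOVA with false-discovery-rate control and
    Spearman hormone-metabolite correlation). A calibrated synthetic
    cohort generator makes the whole pipeline testable without subject
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    pracma,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
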