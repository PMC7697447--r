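Package: traworker
Title: Tier-1 Worker Inhalation Exposure Estimation and Model Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transparent, table-driven re-implementation of the ECETOC TRA
    (Targeted Risk Assessment) worker inhalation exposure model used for
    Tier-1 REACH screening assessment, together with the statistics needed
    to validate it against workplace measurements: the multiplicative
    base-estimate and modifying-factor engine over PROC process categories,
    lognormal exposure summaries and percentiles with exact noncentral-t or
    bootstrap confidence intervals, measurement-dataset curation rules
    (minimum sample size, PROC assignability, contextual completeness,
    control-credit adjustment), estimate-versus-measurement comparison
    verdicts, and a synthetic lognormal measurement generator including a
    compliance-biased sampling strategy.
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
    readr,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    fitdistrplus,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
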