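Package: nearmiss
Title: WHO Maternal Near-Miss Assessment and the Maternal Severity Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for severe-maternal-morbidity surveillance built on the
    World Health Organization maternal near-miss approach. Classifies
    obstetric cases against the 25 WHO life-threatening-condition markers,
    computes the maternal severity score and the Maternal Severity Index
    (MSI, an estimated probability of maternal death from a published
    logistic model), reproduces the diagnostic-accuracy statistics used to
    validate the WHO criteria (sensitivity, specificity, likelihood ratios,
    relative risks, maternal mortality ratio), re-derives MSI-style models
    from line-listed cohorts (logistic regression, stepwise selection,
    Hosmer-Lemeshow, Nagelkerke R-squared, AUROC), and benchmarks facilities
    through observed-versus-expected mortality. A calibrated synthetic
    cohort generator makes every analysis testable without access to
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
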