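# nearmiss

Tools for severe-maternal-morbidity surveillance built on the WHO maternal
near-miss approach, for epidemiologists, obstetric audit teams and health
services researchers.

Maternal deaths are too rare at the level of a single facility to support
quality-of-care assessment on their own. The WHO maternal near-miss approach
widens the lens: women who present any of 25 standardized life-threatening
conditions (severity markers spanning cardiovascular, respiratory, renal,
coagulation/hematological, hepatic, neurological and uterine dysfunction)
and survive are *maternal near misses*, studied as surrogates of maternal
deaths. This package implements the full analysis chain around that
definition:

* **Case classification** — every woman becomes `maternal_death`,
  `maternal_near_miss` or `no_life_threatening_condition`; lab values
  (creatinine, bilirubin, platelets, pH, lactate, PaO2/FiO2, respiratory
  rate, SpO2 duration) are evaluated against the catalog cutoffs in either
  published unit scale.
* **Maternal severity score (MSS)** — the number of distinct severity
  markers present in a case (0–25).
* **Maternal Severity Index (MSI)** — the estimated probability of maternal
  death from a published logistic model over seven covariates:

  ```
  logit = β₀ + x₁β₁ + x₂β₂ + x₃β₃ + x₄β₄ + x₅β₅ + x₆β₆ + x₇β₇
  MSI   = e^logit / (1 + e^logit)
  ```

  with x₁ = severity score, x₂ = condition identified in the first 24 h of
  stay, x₃ = severe pre-eclampsia, x₄ = cancer, x₅ = any
  cardiovascular-failure marker, x₆ = any respiratory-failure marker,
  x₇ = hysterectomy. The packaged default coefficient set (`"souza2012"`,
  from a 27-hospital Brazilian referral-network validation cohort of 82,388
  deliveries) is β = (−7.540, 0.309, 0.287, −0.579, 3.492, 4.209, 1.513,
  −1.169).
* **Validation statistics** — sensitivity/specificity with Wilson intervals,
  likelihood ratios (Simel log method), per-marker relative risks (Katz log
  method), maternal mortality ratio with exact Poisson limits, and the
  score-mortality gradient with its Pearson correlation.
* **Model re-derivation** — logistic fits of MSI-style models on your own
  cohort (score-only "model I", the full covariate set "model II", or
  forward-stepwise selection with likelihood-ratio tests), with
  Hosmer–Lemeshow calibration, Nagelkerke R², AUROC with DeLong intervals,
  seeded development/testing splits and AUROC sample-size planning.
* **Benchmarking** — expected deaths (Σ MSI), observed/expected mortality
  ratios with exact-Poisson SMR intervals, per-facility or per-period
  comparison.
* **Synthetic cohorts** — a calibrated generator (single-factor latent
  threshold model for marker co-occurrence; deaths drawn from the MSI model)
  so every analysis is testable without patient-level data.

All user-facing functions take a data frame of case records first and return
tibbles, so analyses chain with the pipe; fitted models support `tidy()` and
`glance()`, and each result type has a plot function
(`plot_score_mortality()`, `autoplot()` for ROC curves, `plot_benchmark()`).

## Worked example

A 100-case synthetic line listing ships with the package (60 marker-positive
cases, 40 without life-threatening conditions, two facilities):

```r
library(nearmiss)
library(dplyr)

cases <- read_cases(system.file("extdata", "synthetic_cases.csv",
                                package = "nearmiss"))
classify_cases(cases) |> count(category)
#>   category                          n
#> 1 maternal_death                    4
#> 2 maternal_near_miss               56
#> 3 no_life_threatening_condition    40

add_msi(cases) |> select(case_id, severity_score, msi) |>
  arrange(desc(msi)) |> head(3)
#>   case_id  severity_score   msi
#> 1 case_045             17 0.928
#> 2 case_051             17 0.906
#> 3 case_027              9 0.777

benchmark_cohort(cases, by = "facility")
#>   stratum    n_cases n_unmarked mean_severity_score mean_msi expected_deaths
#> 1 hospital_A      30         20                3.33   0.113             3.39
#> 2 hospital_B      30         20                2.63   0.0690            2.07
#> 3 (pooled)        60         40                2.98   0.0910            5.46
#>   observed_deaths    oe  oe_lo oe_hi
#> 1               3 0.886 0.183   2.59
#> 2               1 0.483 0.0122  2.69
#> 3               4 0.733 0.200   1.88
```

The benchmark reads: given each hospital's case-mix (mean severity score 3.3
vs 2.6 among marker-positive cases), the MSI reference standard of care
predicts 3.4 and 2.1 deaths; both observed counts are compatible with O/E = 1,
so neither facility shows excess mortality at this sample size. An O/E well
above 1 would flag possible missed opportunities in care. MSI estimates
benchmark services — they must not directly guide the management of
individual patients.

Published summary statistics are reconstructed the same way from counts:

```r
accuracy_stats(tp = 140, fp = 770, fn = 0, tn = 81478)
#>   statistic     point     lo      hi level method
#> 1 sensitivity   1      0.973   1      0.95 wilson
#> 2 specificity   0.991  0.990   0.991  0.95 wilson
#> 3 plr         107.    99.6   115.     0.95 simel_log
#> 4 nlr           0     NA      NA      0.95 simel_log

mmr(140, 82144)   # 170 maternal deaths per 100,000 live births (143-201)
```

A command-line surface wrapping the same functions ships at
`inst/cli/msi.R` (`simulate`, `classify`, `score`, `validate`, `benchmark`,
`fit`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","msi.R",package="nearmiss"))')" \
  simulate --deliveries 20000 --seed 7 --out cases.csv
```

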