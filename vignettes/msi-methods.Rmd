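---
title: "Methods: the maternal near-miss toolkit and the Maternal Severity Index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the maternal near-miss toolkit and the Maternal Severity Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nearmiss)
```

## The problem

Maternal deaths are rare at facility level, so facility-level quality
assessment built on death counts alone is underpowered. The WHO maternal
near-miss approach treats survivors of pregnancy-related life-threatening
conditions as surrogates of maternal deaths: conceptually, a near miss is as
similar to a death as possible except for the vital status. Two instruments
make this operational:

1. a standardized catalog of 25 severity markers (life-threatening
   conditions) that defines who counts as a near miss, and
2. a logistic death-probability model — the **Maternal Severity Index
   (MSI)** — that converts a case's markers and condition flags into an
   expected mortality, enabling case-mix-adjusted benchmarking of services.

This vignette documents the modelling choices, defaults and limitations of
the package's implementation.

## The marker catalog and classification

`who_marker_catalog()` carries the 25 markers, each assigned to one of seven
organ systems and to group A or group B (group B mirrors SOFA score
categories 3–4, i.e. greater severity; `organ_profile()` reports the dominant
group per system, with B dominating A). Classification is total and
deterministic: deaths are `maternal_death` regardless of markers; surviving
marker-positive cases are `maternal_near_miss`; everyone else has
`no_life_threatening_condition`. A death without any recorded marker is
accepted — input data may be incomplete — but triggers a validation warning,
since in the validation cohort every death presented at least one marker.

**Units.** The source catalog prints creatinine "≥300 mmol/l or ≥3,5 mg/dl"
and bilirubin ">100 mmol/l or >6,0 mg/dl". Those SI magnitudes are only
physiologically coherent as µmol/l (300 µmol/l ≈ 3.4 mg/dl), so the package
stores the printed cutoff numbers verbatim but labels the SI scale µmol/l.
Each unit scale applies its own printed cutoff; inequality strictness follows
the printed symbols exactly (thrombocytopenia "<50 000" is strict; creatinine
"≥300" is not). `evaluate_lab_marker()` rejects unknown analytes and units
rather than guessing, and raw laboratory columns only materialize a marker
when the marker column itself is absent or missing for that row — an explicit
recorded value always wins.

**The maternal severity score** is simply the count of distinct markers
present (0–25). It deliberately counts all 25 markers, including those that
also drive the MSI's cardiovascular/respiratory-failure indicators, because
the index defines its x₁ as the total number of conditions with no
exclusions.

## The MSI model

The MSI is `plogis(β₀ + Σ xᵢβᵢ)` with the covariates

| covariate | meaning | default β |
|---|---|---|
| x₁ | severity score (count, 0–25) | 0.309 |
| x₂ | any condition identified in first 24 h of stay (0/1) | 0.287 |
| x₃ | severe pre-eclampsia (0/1) | −0.579 |
| x₄ | cancer (0/1) | 3.492 |
| x₅ | any of: pH < 7.1, continuous vasoactive drugs, cardiac arrest, CPR | 4.209 |
| x₆ | any of: gasping, PaO2/FiO2 < 200 mmHg, intubation/ventilation not for anesthesia | 1.513 |
| x₇ | hysterectomy for infection or hemorrhage | −1.169 |

with β₀ = −7.540 (coefficient set `"souza2012"`). The negative x₃ and x₇
coefficients are conditional effects, not protective causal claims: at a
given severity level, severe pre-eclampsia is a comparatively manageable
determinant, and hysterectomy is a definitive intervention against
hemorrhage/sepsis. x₂ is interpreted as *any* marker identified within the
first 24 hours (the alternative reading — first marker only — is not
decidable from the published definition; we use "any" and carry the flag as
an explicit input). Severe pre-eclampsia and cancer are input flags, not
derivable from markers. The hysterectomy covariate and the uterine marker
are one and the same boolean. Probabilities are kept at full precision;
rounding to 3 significant digits happens only in the CLI `score` command.

`fit_msi_model()` re-derives MSI-style models from a cohort: `"score_only"`
(model I), `"full"` (the x₁…x₇ set, model II), or `"stepwise"`
(forward-stepwise with likelihood-ratio tests at entry p < 0.05 / removal
p > 0.10, iteration-capped so add/remove cycles terminate). LR tests were
chosen for both entry and removal because they are exactly reproducible;
score-test entry as implemented by some commercial packages agrees closely at
these sample sizes. The fitting engine is `stats::glm` (IRLS);
(quasi-)perfect separation is detected via degenerate fitted probabilities
together with standardized coefficients exceeding 15 and is *reported*, never
silently penalized away. Development/testing splits (`split_cohort()`) are
seeded simple random sampling without stratification by outcome.

**Diagnostics.** `hosmer_lemeshow()` groups cases into deciles of predicted
risk (ties broken by stable sort on probability then case order, group sizes
as equal as possible) and uses χ² = Σ (O−E)²/(n_g p̄(1−p̄)) on g − 2 degrees
of freedom. The χ² null approximation assumes effectively continuous
predicted risks: with the MSI's discrete covariate patterns the fitted
probabilities are heavily tied and the test's p-values are *not* uniform
under the true model (we verified uniformity holds with continuous
covariates and fails with the discrete MSI patterns), so treat
Hosmer–Lemeshow p-values on MSI-type fits as descriptive. `nagelkerke_r2()`
rescales Cox–Snell R² by its maximum. `auroc()` uses the Mann–Whitney
identity with DeLong placement-variance intervals (the interval method for
the AUROC is the package's choice; the source publication does not name
one). `auroc_sample_size()` implements the Hanley–McNeil variance
approximation; the negative:positive ratio is an explicit parameter because
published sample-size statements rarely state it — at the conventional
α = 0.05 (two-sided), power 0.80, null AUROC 0.5 and alternative 0.8, a
balanced design needs 14 positives (28 subjects in total).

## Interval methods

Chosen to reproduce the printed intervals of the validation cohort, and
verified against them in the test suite:

* proportions (sensitivity, specificity, per-score mortality): **Wilson
  score** intervals;
* likelihood ratios: **Simel log method**;
* relative risks: **Katz log method**;
* maternal mortality ratio: **exact Poisson** limits on the death count
  scaled by live births (the exact lower limit for the validation cohort is
  143.4 per 100,000 where 144 is printed — a last-digit artifact of an
  unstated rounding, not reproducible by any standard exact variant we
  tried);
* O/E ratios: exact Poisson limits on the observed count divided by the
  expected count (the classical indirect-standardization convention; the
  source publication gives no interval method for the benchmark, so this is
  the toolkit's labelled convention).

Undefined statistics (zero denominators, likelihood ratios at boundary
sensitivity/specificity, relative risks with a zero-death arm) are flagged in
a `note` column instead of surfacing as silent `NaN`s.

## Benchmarking

`expected_deaths()` is Σ MSI over the cohort; `benchmark_cohort()` reports
per-stratum case counts, mean severity score, mean MSI, expected and observed
deaths and the O/E ratio. The MSI reference population is women with
life-threatening conditions, so by default only marker-positive cases enter
the expected-death sum (the Discussion-style use case: populations treated in
intensive or high-dependency care); unmarked cases are counted separately and
an `include_unmarked` toggle exists. Empty strata are reported with `NA`
statistics, never dropped.

## The synthetic cohort generator

No patient-level data are distributable, so the package ships a generator
(`simulation_config()` + `generate_cohort()`) that emulates a referral-network
surveillance cohort:

* the number of complicated cases is binomial with rate 9,555/82,388 per
  delivery;
* each complicated case draws a latent severity z ~ N(0,1); marker m is
  present iff √ρ·z + √(1−ρ)·ε exceeds the threshold matching that marker's
  configured prevalence (defaults: the validation-cohort marker counts over
  9,555). Marginal prevalences are preserved for every ρ; ρ alone controls
  co-occurrence and hence the tail of the score distribution;
* ρ = 0.7380703 is a frozen package constant, found by deterministic
  bisection (numerical integration of P(score = 0) over the latent factor,
  `calibrate_rho()`) so that the zero-score fraction among complicated cases
  matches the published 8,645/9,555. With this single parameter the full
  score distribution, its mean (0.31 per complicated case) and the
  severe-case fraction (≈ 910 per 82,388 deliveries) track the published
  values closely;
* condition flags: early identification is drawn at rate 0.7 *among
  marker-positive cases* (the flag is defined by a marker in the first
  24 h); severe pre-eclampsia (0.4) and cancer (0.02) are drawn
  independently of markers. These rates are toolkit assumptions typical of a
  referral setting, not published values;
* deaths are Bernoulli(MSI) under the configured coefficient set.

Generating deaths from the MSI model itself (rather than from per-marker
marginal relative risks) makes parameter recovery and O/E calibration
well-posed end-to-end tests. It is also the generator's main departure from
reality, with visible consequences:

* expected mortality among severe cases is ≈ 12%, somewhat below the
  validation cohort's 15.4% — the published marginal death count is not a
  calibration target;
* a score-only model genuinely discriminates less than the full covariate
  model on generated data (AUROC ≈ 0.90 vs ≈ 0.95 across seeds), whereas the
  validation cohort reported near-identical AUROCs (0.955 vs 0.954). That
  near-equality is an empirical feature of the real joint distribution of
  markers that a single-factor latent model does not reproduce. The full
  model's discrimination on generated cohorts (≈ 0.95) does match the
  published range;
* marker-free deaths occur at the baseline rate logistic(−7.540 + flag
  effects) ≈ 5 × 10⁻⁴ — the generator does not force every death to carry a
  marker, and the classification warning fires accordingly.

Passing tests on generated cohorts therefore demonstrate correctness of the
statistical machinery under a plausible data-generating process, not
real-world performance of the MSI in a new population.

## Problem sizes and numerical choices

The test suite exercises parameter recovery on 100 cohorts of 8,000 severe
cases (recovery is asserted as ≈ 95% coverage of per-replicate Wald
intervals, which is robust to the small O(1/n) bias of maximum likelihood at
these event counts, rather than as a vanishing mean bias), O/E calibration
over 200 simulated facility cohorts of 500 severe cases, AUROC equivalence
against an O(n²) concordance count at n = 400, and Hosmer–Lemeshow p-value
uniformity over 200 refit replicates of a continuous-covariate logistic
model of size 1,500. The acceptance script repeats the deterministic
reconstructions and scaled-down seeded versions of the simulations.

Other numerical conventions: all randomness flows from explicit seeds
(`with_seed` isolates the RNG state, and the CLI exposes a single `--seed`);
intercept-only fits define Nagelkerke R² = 0; empty Hosmer–Lemeshow groups
reduce the group count with a message; booleans in CSVs accept
{0, 1, true, false, yes, no} case-insensitively and anything else is an
error, never a guess.

## Known limitations

* The MSI reflects the standard of care of the 2009–2010 Brazilian referral
  cohort that produced its coefficients; O/E = 1 means "as expected under
  that reference", not "optimal".
* The broader inclusion criterion of surveillance (women with *potentially*
  life-threatening conditions) has no operational definition here; cohort
  membership is an input, not something the package computes.
* The generator does not model referral dynamics, delays in care, perinatal
  outcomes, or any joint marker structure beyond a single latent factor.
* MSI estimates must not directly guide the management of individual
  patients; a woman with MSI 0.95 may well be among the survivors. The CLI
  prints this caveat in its report footers.
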