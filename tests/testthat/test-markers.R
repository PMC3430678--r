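test_that("the catalog holds exactly the 25 WHO markers with valid metadata", {
  cat <- who_marker_catalog()
  expect_equal(nrow(cat), 25L)
  expect_equal(anyDuplicated(cat$marker_id), 0L)
  expect_setequal(unique(cat$organ_system),
                  c("cardiovascular", "respiratory", "renal",
                    "coagulation/hematological", "hepatic", "neurological",
                    "uterine"))
  expect_true(all(cat$group %in% c("A", "B")))
  # group B membership: the greater-severity (SOFA 3-4) markers
  expect_setequal(cat$marker_id[cat$group == "B"],
                  c("ph_low", "vasoactive_drugs", "cardiac_arrest", "cpr",
                    "gasping", "pao2_fio2_low", "intubation",
                    "creatinine_high", "dialysis", "thrombocytopenia",
                    "bilirubin_high", "coma_12h"))
  # per-system marker counts
  expect_equal(as.vector(table(cat$organ_system)[c(
    "cardiovascular", "respiratory", "renal", "coagulation/hematological",
    "hepatic", "neurological", "uterine")]), c(6L, 6L, 3L, 3L, 2L, 4L, 1L))
})

test_that("lab thresholds honour printed cutoffs, strictness and units", {
  expect_true(evaluate_lab_marker("creatinine", 3.5, "mg/dl"))   # >= 3.5
  expect_false(evaluate_lab_marker("creatinine", 3.49, "mg/dl"))
  expect_true(evaluate_lab_marker("creatinine", 300, "umol/l"))
  expect_false(evaluate_lab_marker("platelets", 50000, "per_ul")) # strict <
  expect_true(evaluate_lab_marker("platelets", 49999, "per_ul"))
  expect_true(evaluate_lab_marker("platelets", 49, "x10e9_per_l"))
  expect_false(evaluate_lab_marker("ph", 7.10, "unitless"))       # strict <
  expect_true(evaluate_lab_marker("ph", 7.09, "unitless"))
  expect_false(evaluate_lab_marker("lactate", 5, "mmol/l"))       # strict >
  expect_true(evaluate_lab_marker("lactate", 5.01, "mmol/l"))
  expect_false(evaluate_lab_marker("bilirubin", 100, "umol/l"))   # strict >
  expect_true(evaluate_lab_marker("bilirubin", 100.5, "umol/l"))
  expect_true(evaluate_lab_marker("bilirubin", 6.1, "mg/dl"))
  # respiratory rate is out of range on either side
  expect_equal(evaluate_lab_marker("respiratory_rate", c(41, 40, 20, 6, 5),
                                   "per_min"),
               c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_true(evaluate_lab_marker("spo2_duration", 60, "min"))    # >= 60
  expect_false(evaluate_lab_marker("spo2_duration", 59, "min"))
  expect_true(evaluate_lab_marker("pao2_fio2", 199, "mmhg"))
  expect_false(evaluate_lab_marker("pao2_fio2", 200, "mmhg"))
})

test_that("unknown analytes and units are rejected, never coerced", {
  expect_error(evaluate_lab_marker("hemoglobin", 7, "g/dl"), "Unknown analyte")
  expect_error(evaluate_lab_marker("creatinine", 3.5, "mmol/l"), "Unknown unit")
  expect_error(evaluate_lab_marker("creatinine", -1, "mg/dl"), "Negative")
})

test_that("classification partitions any cohort into the three categories", {
  cases <- make_cases(markers = list("shock", character(0), "cpr",
                                     character(0)),
                      died = c(FALSE, FALSE, TRUE, FALSE))
  out <- classify_cases(cases)
  expect_equal(as.character(out$category),
               c("maternal_near_miss", "no_life_threatening_condition",
                 "maternal_death", "no_life_threatening_condition"))
  expect_false(anyNA(out$category))
  # reproduces the published cohort structure: 140 deaths + 770 positive
  # survivors + 8645 unmarked survivors
  big <- make_cases(markers = c(rep(list("shock"), 910),
                                rep(list(character(0)), 8645)),
                    died = c(rep(TRUE, 140), rep(FALSE, 9415)))
  counts <- table(classify_cases(big)$category)
  expect_equal(as.vector(counts),
               c(140L, 770L, 8645L))
})

test_that("a death with no recorded marker is accepted but flagged", {
  cases <- make_cases(markers = list(character(0)), died = TRUE)
  expect_warning(out <- classify_cases(cases), "without any recorded")
  expect_equal(as.character(out$category), "maternal_death")
})

test_that("severity score counts distinct markers and is monotone", {
  expect_equal(severity_score(make_cases(list(character(0)))), 0L)
  expect_equal(severity_score(make_cases(list(c("shock", "cpr",
                                                "cardiac_arrest")))), 3L)
  # monotone under marker addition, property over random marker sets
  set.seed(42)
  for (i in 1:25) {
    base <- sample(marker_ids(), sample(0:20, 1))
    extra <- sample(setdiff(marker_ids(), base), 1)
    s0 <- severity_score(make_cases(list(base)))
    s1 <- severity_score(make_cases(list(c(base, extra))))
    expect_identical(s1, s0 + 1L)
  }
})

test_that("organ profile reports the dominant group per system", {
  prof <- organ_profile(make_cases(list("shock")))
  expect_equal(nrow(prof), 7L)
  expect_equal(as.character(prof$level[prof$organ_system == "cardiovascular"]),
               "groupA_only")
  prof2 <- organ_profile(make_cases(list(c("shock", "cpr"))))
  expect_equal(as.character(prof2$level[prof2$organ_system == "cardiovascular"]),
               "groupB")
  prof0 <- organ_profile(make_cases(list(character(0))))
  expect_true(all(prof0$level == "none"))
})

test_that("catalog JSON export round-trips the marker set", {
  path <- withr::local_tempfile(fileext = ".json")
  write_marker_catalog_json(path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$markers$marker_id, marker_ids())
  expect_equal(nrow(back$lab_thresholds), 12L)
})
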