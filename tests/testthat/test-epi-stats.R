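test_that("accuracy statistics match a per-case enumeration oracle", {
  # oracle: build the case list, tally the 2x2 by looping, compute naively
  set.seed(7)
  for (rep in 1:5) {
    n <- 400
    crit <- sample(c(TRUE, FALSE), n, replace = TRUE)
    died <- stats::runif(n) < ifelse(crit, 0.3, 0.05)
    tp <- 0; fp <- 0; fn <- 0; tn <- 0
    for (i in seq_len(n)) {
      if (died[i] && crit[i]) tp <- tp + 1
      if (!died[i] && crit[i]) fp <- fp + 1
      if (died[i] && !crit[i]) fn <- fn + 1
      if (!died[i] && !crit[i]) tn <- tn + 1
    }
    got <- accuracy_stats(tp, fp, fn, tn)
    expect_equal(got$point[got$statistic == "sensitivity"], tp / (tp + fn))
    expect_equal(got$point[got$statistic == "specificity"], tn / (tn + fp))
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    expect_equal(got$point[got$statistic == "plr"], sens / (1 - spec))
    expect_equal(got$point[got$statistic == "nlr"], (1 - sens) / spec)
  }
})

test_that("degenerate two-by-two tables are flagged, not NaN", {
  perfect <- accuracy_stats(10, 0, 0, 10)
  expect_equal(perfect$point[perfect$statistic == "sensitivity"], 1)
  expect_equal(perfect$point[perfect$statistic == "specificity"], 1)
  expect_true(is.na(perfect$point[perfect$statistic == "plr"]))
  expect_match(perfect$note[perfect$statistic == "plr"], "undefined")
  expect_equal(perfect$point[perfect$statistic == "nlr"], 0)
  expect_error(accuracy_stats(0, 5, 0, 5), "deaths")
})

test_that("Wilson intervals agree with prop.test and respect [0,1]", {
  # independent route: stats::prop.test without continuity correction is the
  # Wilson score interval
  for (kn in list(c(14, 61), c(0, 402), c(140, 140), c(1, 3), c(999, 1000))) {
    ours <- proportion_ci(kn[1], kn[2])
    ref <- suppressWarnings(
      stats::prop.test(kn[1], kn[2], correct = FALSE)$conf.int)
    expect_equal(c(ours$lo, ours$hi), as.numeric(ref), tolerance = 1e-10)
  }
  # bounds property over a grid
  set.seed(11)
  n <- pmax(1, round(10^stats::runif(60, 0, 6)))
  k <- vapply(n, function(m) sample(0:m, 1), numeric(1))
  for (i in seq_along(n)) {
    ci <- proportion_ci(k[i], n[i])
    expect_true(ci$lo >= 0 && ci$hi <= 1 && ci$lo <= ci$point &&
                  ci$point <= ci$hi)
  }
  expect_equal(proportion_ci(0, 1)$point, 0)
  expect_equal(proportion_ci(0, 1)$lo, 0)
  expect_error(proportion_ci(1, 0), "positive")
})

test_that("relative risk reproduces closed forms and scale invariance", {
  expect_equal(relative_risk(5, 100, 50, 1000)$point, 1.0)
  rr <- relative_risk(74, 250, 66, 9305)
  expect_equal(rr$point, (74 / 250) / (66 / 9305))
  # scaling both arms by an integer factor keeps the point estimate
  rr4 <- relative_risk(4 * 74, 4 * 250, 4 * 66, 4 * 9305)
  expect_equal(rr4$point, rr$point)
  # zero deaths in an arm: flagged, no log-method CI
  z <- relative_risk(0, 50, 10, 100)
  expect_equal(z$point, 0)
  expect_true(is.na(z$lo))
  expect_match(z$note, "zero deaths")
  zi <- relative_risk(5, 50, 0, 100)
  expect_true(is.infinite(zi$point))
})

test_that("plr > 1 iff nlr < 1 for informative tables", {
  set.seed(3)
  for (i in 1:30) {
    t <- sample(5:200, 4, replace = TRUE)
    st <- accuracy_stats(t[1], t[2], t[3], t[4])
    sens <- st$point[st$statistic == "sensitivity"]
    spec <- st$point[st$statistic == "specificity"]
    if (sens > 0 && sens < 1 && spec > 0 && spec < 1) {
      plr <- st$point[st$statistic == "plr"]
      nlr <- st$point[st$statistic == "nlr"]
      expect_equal(plr > 1, nlr < 1)
    }
  }
})

test_that("mmr uses exact Poisson limits on the death count", {
  out <- mmr(0, 1000)
  expect_equal(out$point, 0)
  expect_equal(out$lo, 0)
  # exact upper limit for zero events is -ln(0.025) ~= 3.689 events
  expect_equal(out$hi, -log(0.025) / 1000 * 1e5, tolerance = 1e-9)
  expect_equal(mmr(100000, 100000)$point, 1e5)
  expect_error(mmr(10, 0), "positive")
})

test_that("score-mortality table bins, caps and correlates correctly", {
  counts <- validation_cohort_counts()$score_distribution
  cohort <- cohort_from_score_distribution(counts$score, counts$n,
                                           counts$deaths)
  tab <- score_mortality_table(cohort, cap = 15)
  expect_equal(nrow(tab), 16L)
  expect_equal(tab$score_bin[16], "15+")
  expect_equal(tab$n, counts$n)
  expect_equal(tab$deaths, counts$deaths)
  row4 <- tab[tab$score_bin == "4", ]
  expect_equal(row4$mortality, 14 / 61)
  expect_equal(c(row4$lo, row4$hi), c(0.1419323, 0.3491341),
               tolerance = 1e-6)
  # all-survivor cohort: correlation undefined and flagged
  flat <- make_cases(rep(list("shock"), 10), died = FALSE)
  expect_warning(t2 <- score_mortality_table(flat), "zero variance")
  expect_true(is.na(score_mortality_correlation(t2)))
  # two bins with increasing mortality: correlation exactly 1
  two <- dplyr::bind_rows(
    make_cases(rep(list("shock"), 10), died = c(TRUE, rep(FALSE, 9))),
    make_cases(rep(list(c("shock", "cpr")), 10),
               died = c(rep(TRUE, 5), rep(FALSE, 5))))
  expect_equal(score_mortality_correlation(score_mortality_table(two)), 1.0)
})

test_that("the marker table reconstructs per-marker epidemiology", {
  # cohort where one marker is a perfect predictor of death
  cohort <- dplyr::bind_rows(
    make_cases(rep(list("cpr"), 20), died = TRUE),
    make_cases(rep(list("shock"), 30), died = FALSE),
    make_cases(rep(list(character(0)), 50), died = FALSE))
  tab <- marker_table(cohort, deliveries = 1000)
  cpr <- tab[tab$marker_id == "cpr", ]
  expect_equal(cpr$deaths, 20L)
  expect_equal(cpr$mortality, 1)
  expect_equal(cpr$prevalence_per_1000, 20)
  expect_true(is.infinite(cpr$rr)) # no deaths among the unexposed
  shock <- tab[tab$marker_id == "shock", ]
  expect_equal(shock$deaths, 0L)
  expect_equal(shock$survivors, 30L)
  absent <- tab[tab$marker_id == "stroke", ]
  expect_match(absent$note, "no cases")
  expect_equal(nrow(tab), 25L) # absent markers reported, not dropped
})
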