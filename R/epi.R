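#' Wilson score interval for a binomial proportion
#'
#' @param k Number of events.
#' @param n Number of trials (> 0).
#' @param level Confidence level (default 0.95).
#' @return A one-row tibble: `point`, `lo`, `hi`, `level`, `method`.
#' @examples
#' proportion_ci(14, 61) # 23% (14.2%-34.9%)
#' @export
proportion_ci <- function(k, n, level = 0.95) {
  stopifnot(length(k) == 1L, length(n) == 1L)
  if (n <= 0) stop("`n` must be positive.", call. = FALSE)
  if (k < 0 || k > n) stop("`k` must lie in [0, n].", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  tibble::tibble(point = p, lo = max(0, centre - half),
                 hi = min(1, centre + half), level = level, method = "wilson")
}

# exact Poisson limits for an event count
poisson_count_ci <- function(k, level = 0.95) {
  a <- 1 - level
  lo <- if (k == 0) 0 else stats::qchisq(a / 2, 2 * k) / 2
  hi <- stats::qchisq(1 - a / 2, 2 * k + 2) / 2
  c(lo = lo, hi = hi)
}

#' Diagnostic accuracy of a death-prediction criterion
#'
#' Computes sensitivity, specificity and the positive/negative likelihood
#' ratios from a 2x2 table of maternal deaths against criterion positivity,
#' with confidence intervals: Wilson score intervals for the proportions and
#' log-method intervals for the likelihood ratios.
#'
#' Statistics with an undefined value or interval (zero denominators, a
#' boundary sensitivity/specificity for the log method) are flagged in the
#' `note` column rather than silently returned as `NaN`.
#'
#' @param tp,fp,fn,tn Counts: deaths that are criterion-positive (`tp`),
#'   survivors criterion-positive (`fp`), deaths criterion-negative (`fn`),
#'   survivors criterion-negative (`tn`).
#' @param level Confidence level.
#' @return A tibble with one row per statistic (`sensitivity`, `specificity`,
#'   `plr`, `nlr`): `point`, `lo`, `hi`, `level`, `method`, `note`.
#' @examples
#' accuracy_stats(tp = 140, fp = 770, fn = 0, tn = 81478)
#' @export
accuracy_stats <- function(tp, fp, fn, tn, level = 0.95) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("Counts must be non-negative.", call. = FALSE)
  if (tp + fn == 0 || tn + fp == 0) {
    stop("Both deaths (tp + fn) and survivors (fp + tn) must be present.",
         call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  sens_ci <- proportion_ci(tp, tp + fn, level)
  spec_ci <- proportion_ci(tn, tn + fp, level)

  lr_row <- function(name, point, se_terms, defined, note_undef) {
    if (!defined) {
      return(tibble::tibble(statistic = name, point = point, lo = NA_real_,
                            hi = NA_real_, level = level, method = "simel_log",
                            note = note_undef))
    }
    se <- sqrt(sum(se_terms))
    tibble::tibble(statistic = name, point = point,
                   lo = point * exp(-z * se), hi = point * exp(z * se),
                   level = level, method = "simel_log", note = NA_character_)
  }

  # PLR = sens/(1-spec); log-method SE uses 1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn)
  plr <- if (spec == 1) {
    tibble::tibble(statistic = "plr", point = NA_real_, lo = NA_real_,
                   hi = NA_real_, level = level, method = "simel_log",
                   note = "undefined: specificity = 1")
  } else {
    lr_row("plr", sens / (1 - spec),
           c(if (tp > 0) 1 / tp - 1 / (tp + fn) else NA_real_,
             1 / fp - 1 / (fp + tn)),
           defined = tp > 0,
           note_undef = "CI undefined: no true positives")
  }
  # NLR = (1-sens)/spec; with fn = 0 the point is 0 and the log CI undefined
  nlr <- if (spec == 0) {
    tibble::tibble(statistic = "nlr", point = NA_real_, lo = NA_real_,
                   hi = NA_real_, level = level, method = "simel_log",
                   note = "undefined: specificity = 0")
  } else if (fn == 0) {
    tibble::tibble(statistic = "nlr", point = 0, lo = NA_real_, hi = NA_real_,
                   level = level, method = "simel_log",
                   note = "CI undefined by log method: zero false negatives")
  } else {
    lr_row("nlr", (1 - sens) / spec,
           c(1 / fn - 1 / (tp + fn), 1 / tn - 1 / (fp + tn)),
           defined = tn > 0, note_undef = "CI undefined: no true negatives")
  }

  dplyr::bind_rows(
    tibble::tibble(statistic = "sensitivity", point = sens, lo = sens_ci$lo,
                   hi = sens_ci$hi, level = level, method = "wilson",
                   note = NA_character_),
    tibble::tibble(statistic = "specificity", point = spec, lo = spec_ci$lo,
                   hi = spec_ci$hi, level = level, method = "wilson",
                   note = NA_character_),
    plr, nlr
  )
}

#' Relative risk with Katz log-method confidence interval
#'
#' @param exposed_deaths,exposed_total Deaths and total in the exposed arm
#'   (e.g. cases presenting a severity marker).
#' @param unexposed_deaths,unexposed_total Deaths and total in the reference
#'   arm.
#' @param level Confidence level.
#' @return A one-row tibble: `point`, `lo`, `hi`, `level`, `method`, `note`.
#' @examples
#' relative_risk(74, 250, 66, 9305) # shock: RR 41.7 (30.7-56.7)
#' @export
relative_risk <- function(exposed_deaths, exposed_total,
                          unexposed_deaths, unexposed_total, level = 0.95) {
  if (exposed_total <= 0 || unexposed_total <= 0) {
    stop("Arm totals must be positive.", call. = FALSE)
  }
  r1 <- exposed_deaths / exposed_total
  r0 <- unexposed_deaths / unexposed_total
  if (exposed_deaths == 0 || unexposed_deaths == 0) {
    point <- if (unexposed_deaths == 0 && exposed_deaths > 0) Inf else r1 / max(r0, .Machine$double.xmin)
    if (exposed_deaths == 0) point <- 0
    return(tibble::tibble(point = point, lo = NA_real_, hi = NA_real_,
                          level = level, method = "katz_log",
                          note = "CI not computable by log method: zero deaths in an arm"))
  }
  rr <- r1 / r0
  se <- sqrt(1 / exposed_deaths - 1 / exposed_total +
             1 / unexposed_deaths - 1 / unexposed_total)
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(point = rr, lo = exp(log(rr) - z * se),
                 hi = exp(log(rr) + z * se), level = level,
                 method = "katz_log", note = NA_character_)
}

#' Maternal mortality ratio per 100,000 live births
#'
#' Point estimate `deaths / live_births * 1e5` with a confidence interval
#' from exact Poisson limits on the death count scaled by the denominator.
#'
#' @param deaths Number of maternal deaths.
#' @param live_births Number of live births (> 0).
#' @param level Confidence level.
#' @return A one-row tibble: `point`, `lo`, `hi`, `level`, `method` (all per
#'   100,000 live births).
#' @examples
#' mmr(140, 82144) # 170 per 100,000 (143-201)
#' @export
mmr <- function(deaths, live_births, level = 0.95) {
  if (live_births <= 0) stop("`live_births` must be positive.", call. = FALSE)
  if (deaths < 0) stop("`deaths` must be non-negative.", call. = FALSE)
  ci <- poisson_count_ci(deaths, level)
  tibble::tibble(point = deaths / live_births * 1e5,
                 lo = ci[["lo"]] / live_births * 1e5,
                 hi = ci[["hi"]] / live_births * 1e5,
                 level = level, method = "exact_poisson")
}

#' Mortality by maternal severity score
#'
#' Bins a cohort by severity score (0, 1, ..., `cap - 1`, and an open
#' `"cap+"` bin), reports per-bin mortality with Wilson intervals, and the
#' Pearson correlation between the bin's score value (the open bin coded as
#' `cap`) and its mortality proportion — the score-gradient summary used to
#' show that mortality rises with the number of life-threatening conditions.
#'
#' @param cases A case-record data frame.
#' @param cap Score value at which the open top bin starts (default 15).
#' @return A tibble with one row per non-empty bin: `score_bin` (label),
#'   `score_value` (numeric coding used for the correlation), `n`, `deaths`,
#'   `mortality`, `lo`, `hi`. The Pearson correlation is attached as
#'   attribute `"pearson_r"` (also retrievable with
#'   [score_mortality_correlation()]); it is `NA` with a warning when the
#'   per-bin mortality has zero variance.
#' @export
score_mortality_table <- function(cases, cap = 15) {
  if (nrow(cases) == 0L) stop("Empty cohort.", call. = FALSE)
  score <- severity_score(cases)
  died <- parse_bool(cases$died, "died")
  value <- pmin(score, cap)
  tab <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(value = value, died = died), .data$value),
    n = dplyr::n(), deaths = sum(.data$died), .groups = "drop"
  )
  tab <- dplyr::arrange(tab, .data$value)
  ci <- purrr::map2(tab$deaths, tab$n, proportion_ci)
  out <- tibble::tibble(
    score_bin = ifelse(tab$value >= cap, paste0(cap, "+"),
                       as.character(tab$value)),
    score_value = as.numeric(tab$value),
    n = tab$n,
    deaths = tab$deaths,
    mortality = purrr::map_dbl(ci, "point"),
    lo = purrr::map_dbl(ci, "lo"),
    hi = purrr::map_dbl(ci, "hi")
  )
  r <- if (nrow(out) < 2L || stats::sd(out$mortality) == 0 ||
           stats::sd(out$score_value) == 0) {
    warning("Pearson correlation undefined: zero variance across bins.",
            call. = FALSE)
    NA_real_
  } else {
    stats::cor(out$score_value, out$mortality)
  }
  attr(out, "pearson_r") <- r
  out
}

#' @rdname score_mortality_table
#' @param table A table returned by [score_mortality_table()].
#' @export
score_mortality_correlation <- function(table) attr(table, "pearson_r")

#' Per-marker mortality and relative-risk table
#'
#' For each WHO severity marker: deaths and survivors among cases presenting
#' it, prevalence per 1000 deliveries, condition-specific mortality, and the
#' relative risk of death versus cases in the cohort lacking that marker
#' (Katz log-method CI).
#'
#' @param cases A case-record data frame — the complication cohort within
#'   which relative risks are computed.
#' @param deliveries Total deliveries in the surveillance population, the
#'   denominator of the prevalence column.
#' @param level Confidence level for the RR interval.
#' @return A tibble with one row per catalog marker: `marker_id`, `label`,
#'   `deaths`, `survivors`, `prevalence_per_1000`, `mortality`, `rr`, `rr_lo`,
#'   `rr_hi`, `note`. Markers absent from the cohort get `NA` statistics.
#' @export
marker_table <- function(cases, deliveries, level = 0.95) {
  if (deliveries <= 0) stop("`deliveries` must be positive.", call. = FALSE)
  catalog <- who_marker_catalog()
  died <- parse_bool(cases$died, "died")
  n <- nrow(cases)
  rows <- purrr::map(catalog$marker_id, function(id) {
    present <- cases[[id]] %in% TRUE
    n1 <- sum(present)
    d1 <- sum(died & present)
    n0 <- n - n1
    d0 <- sum(died) - d1
    if (n1 == 0L) {
      return(tibble::tibble(marker_id = id, deaths = 0L, survivors = 0L,
                            prevalence_per_1000 = 0, mortality = NA_real_,
                            rr = NA_real_, rr_lo = NA_real_, rr_hi = NA_real_,
                            note = "no cases with this marker"))
    }
    risk <- relative_risk(d1, n1, d0, n0, level)
    tibble::tibble(marker_id = id, deaths = as.integer(d1),
                   survivors = as.integer(n1 - d1),
                   prevalence_per_1000 = n1 / deliveries * 1000,
                   mortality = d1 / n1,
                   rr = risk$point, rr_lo = risk$lo, rr_hi = risk$hi,
                   note = risk$note)
  })
  dplyr::left_join(catalog[, c("marker_id", "label", "organ_system")],
                   dplyr::bind_rows(rows), by = "marker_id")
}
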