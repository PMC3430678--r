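#' Expected maternal deaths in a cohort
#'
#' The sum of per-case MSI values: with an average MSI of 10% across 100
#' women, 10 maternal deaths are expected.
#'
#' @param cases A case-record data frame.
#' @param coef MSI coefficient set (see [msi_coefficients()]).
#' @return A single number, the expected death count.
#' @export
expected_deaths <- function(cases, coef = msi_coefficients()) {
  if (nrow(cases) == 0L) stop("Empty cohort.", call. = FALSE)
  sum(msi_probability(cases, coef))
}

#' Observed/expected mortality ratio
#'
#' Point estimate `observed / expected` with a confidence interval from exact
#' Poisson limits on the observed count divided by the expected count (the
#' classical indirect-standardization convention for standardized mortality
#' ratios). The published MSI work gives no interval method for this
#' benchmark; the Poisson convention is this toolkit's choice and is labelled
#' as such in the `method` column.
#'
#' An O/E above 1 suggests more deaths than the reference standard of care
#' would produce for this case-mix — possible missed opportunities in care.
#'
#' @param observed Observed death count.
#' @param expected Expected death count (> 0).
#' @param level Confidence level.
#' @return A one-row tibble: `point`, `lo`, `hi`, `level`, `method`.
#' @examples
#' oe_ratio(20, 10) # twice the expected mortality
#' @export
oe_ratio <- function(observed, expected, level = 0.95) {
  if (observed < 0) stop("`observed` must be non-negative.", call. = FALSE)
  if (!(expected > 0)) {
    stop("O/E not comparable: expected deaths must be positive.",
         call. = FALSE)
  }
  ci <- poisson_count_ci(observed, level)
  tibble::tibble(point = observed / expected, lo = ci[["lo"]] / expected,
                 hi = ci[["hi"]] / expected, level = level,
                 method = "exact_poisson_smr")
}

#' Benchmark a cohort (or strata of it) against the MSI reference
#'
#' Produces the observed-versus-expected mortality report used for facility
#' and period comparisons: cohort size, mean severity score, mean MSI,
#' expected deaths (sum of MSI), observed deaths, and the O/E ratio with its
#' interval. With a `by` column the report carries one row per stratum plus a
#' pooled row; strata with no eligible cases are reported with `NA`
#' statistics, never dropped.
#'
#' The MSI reference population is women with life-threatening conditions,
#' so by default only cases with at least one severity marker enter the
#' expected-death sum; the remaining cases are counted in `n_unmarked`. Set
#' `include_unmarked = TRUE` to score every case.
#'
#' MSI estimates benchmark services; they must not directly guide the
#' management of individual patients.
#'
#' @param cases A case-record data frame including `died`.
#' @param by Optional name of a stratum column (e.g. `"facility"`).
#' @param coef MSI coefficient set.
#' @param include_unmarked Score cases without any severity marker too
#'   (default `FALSE`).
#' @param level Confidence level for the O/E interval.
#' @return A tibble of class `nearmiss_benchmark`, one row per stratum (plus
#'   `"(pooled)"` when `by` is given): `stratum`, `n_cases`, `n_unmarked`,
#'   `mean_severity_score`, `mean_msi`, `expected_deaths`, `observed_deaths`,
#'   `oe`, `oe_lo`, `oe_hi`.
#' @export
benchmark_cohort <- function(cases, by = NULL, coef = msi_coefficients(),
                             include_unmarked = FALSE, level = 0.95) {
  if (nrow(cases) == 0L) stop("Empty cohort.", call. = FALSE)
  scored <- add_msi(cases, coef)
  scored$.died <- parse_bool(scored$died, "died")

  one <- function(df, label) {
    eligible <- if (include_unmarked) rep(TRUE, nrow(df)) else df$severity_score > 0L
    el <- df[eligible, , drop = FALSE]
    if (nrow(el) == 0L) {
      return(tibble::tibble(
        stratum = label, n_cases = 0L, n_unmarked = nrow(df),
        mean_severity_score = NA_real_, mean_msi = NA_real_,
        expected_deaths = NA_real_, observed_deaths = sum(df$.died),
        oe = NA_real_, oe_lo = NA_real_, oe_hi = NA_real_
      ))
    }
    expd <- sum(el$msi)
    obs <- sum(el$.died)
    ci <- oe_ratio(obs, expd, level)
    tibble::tibble(
      stratum = label, n_cases = nrow(el), n_unmarked = sum(!eligible),
      mean_severity_score = mean(el$severity_score), mean_msi = mean(el$msi),
      expected_deaths = expd, observed_deaths = obs,
      oe = ci$point, oe_lo = ci$lo, oe_hi = ci$hi
    )
  }

  out <- if (is.null(by)) {
    one(scored, "(all)")
  } else {
    if (!by %in% names(scored)) {
      stop("No stratum column `", by, "` in the cohort.", call. = FALSE)
    }
    labels <- unique(as.character(scored[[by]]))
    dplyr::bind_rows(
      purrr::map(labels,
                 function(l) one(scored[as.character(scored[[by]]) == l, ], l)),
      one(scored, "(pooled)")
    )
  }
  class(out) <- c("nearmiss_benchmark", class(out))
  attr(out, "coefficient_set") <- attr(coef, "set_name")
  out
}

#' @export
print.nearmiss_benchmark <- function(x, ...) {
  NextMethod()
  cat("\nCoefficient set:", attr(x, "coefficient_set") %||% "custom", "\n")
  cat("Note: MSI estimates benchmark services; they must not directly\n")
  cat("guide the management of critically ill patients.\n")
  invisible(x)
}
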