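#' MSI coefficient sets
#'
#' The Maternal Severity Index (MSI) is the estimated probability of maternal
#' death from a logistic model over seven covariates:
#' \deqn{logit = \beta_0 + x_1\beta_1 + \dots + x_7\beta_7, \quad
#'       MSI = e^{logit} / (1 + e^{logit})}
#' where \eqn{x_1} is the maternal severity score (number of life-threatening
#' conditions) and \eqn{x_2 \dots x_7} are binary indicators for: conditions
#' identified in the first 24 h of hospital stay, severe pre-eclampsia,
#' cancer, any cardiovascular-failure marker (pH <7.1, continuous vasoactive
#' drugs, cardiac arrest, CPR), any respiratory-failure marker (gasping,
#' PaO2/FiO2 <200 mmHg, intubation/ventilation not related to anesthesia),
#' and hysterectomy.
#'
#' The default set `"souza2012"` carries the published coefficients from the
#' 2009--2010 Brazilian multicenter validation cohort:
#' \eqn{\beta_0 = -7.540}, \eqn{\beta_1 = 0.309}, \eqn{\beta_2 = 0.287},
#' \eqn{\beta_3 = -0.579}, \eqn{\beta_4 = 3.492}, \eqn{\beta_5 = 4.209},
#' \eqn{\beta_6 = 1.513}, \eqn{\beta_7 = -1.169}.
#'
#' @param set Name of a packaged coefficient set (currently `"souza2012"`), or
#'   the path of a JSON file with fields `beta0` ... `beta7` (as written by
#'   [write_msi_coefficients()] or produced from a refitted model).
#' @return A named numeric vector of length 8 with names `beta0` ... `beta7`
#'   and attribute `set_name`.
#' @export
msi_coefficients <- function(set = "souza2012") {
  if (is.numeric(set)) {
    coef <- set
  } else if (set == "souza2012") {
    coef <- c(beta0 = -7.540, beta1 = 0.309, beta2 = 0.287, beta3 = -0.579,
              beta4 = 3.492, beta5 = 4.209, beta6 = 1.513, beta7 = -1.169)
  } else if (file.exists(set)) {
    raw <- jsonlite::read_json(set, simplifyVector = TRUE)
    coef <- unlist(raw[paste0("beta", 0:7)])
  } else {
    stop("Unknown coefficient set '", set,
         "': not a packaged name and not an existing file.", call. = FALSE)
  }
  nm <- paste0("beta", 0:7)
  if (!all(nm %in% names(coef))) {
    stop("A coefficient set needs the 8 named elements beta0...beta7.",
         call. = FALSE)
  }
  out <- coef[nm]
  attr(out, "set_name") <- if (is.character(set)) set else "custom"
  out
}

#' Write an MSI coefficient set to JSON
#'
#' @param coef A named vector as returned by [msi_coefficients()] or the
#'   coefficients of a fit from [fit_msi_model()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_msi_coefficients <- function(coef, path) {
  jsonlite::write_json(as.list(coef), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Derive the MSI covariates from case records
#'
#' Computes the covariate vector \eqn{x_1 \dots x_7} feeding the MSI logistic
#' model: the severity score, the three condition flags, the
#' cardiovascular-failure and respiratory-failure indicators (unions over
#' their marker groups), and hysterectomy. The severity score deliberately
#' counts all 25 markers, including those that also drive the x5/x6/x7
#' indicators.
#'
#' @param cases A case-record data frame (see [as_case_records()]).
#' @return A tibble with columns `case_id` and `x1` ... `x7` (`x1` integer,
#'   the rest 0/1).
#' @examples
#' rec <- as_case_records(data.frame(cpr = 1, intubation = 1,
#'                                   early_identification = 1, died = 0))
#' derive_covariates(rec)
#' @export
derive_covariates <- function(cases) {
  any_of_markers <- function(set) {
    m <- as.matrix(dplyr::mutate(cases[set], dplyr::across(dplyr::everything(),
                                                           ~ .x %in% TRUE)))
    as.integer(rowSums(m) > 0)
  }
  tibble::tibble(
    case_id = cases$case_id,
    x1 = severity_score(cases),
    x2 = as.integer(cases$early_identification %in% TRUE),
    x3 = as.integer(cases$severe_preeclampsia %in% TRUE),
    x4 = as.integer(cases$cancer %in% TRUE),
    x5 = any_of_markers(cardiovascular_failure_markers),
    x6 = any_of_markers(respiratory_failure_markers),
    x7 = as.integer(cases$hysterectomy %in% TRUE)
  )
}

#' Maternal Severity Index (estimated death probability)
#'
#' `msi_probability()` returns the per-case MSI as a numeric vector;
#' `add_msi()` appends `severity_score` and `msi` columns to the cohort,
#' which is the shape consumed by the benchmarking functions.
#'
#' The MSI is an epidemiological benchmarking quantity; it must not directly
#' guide the clinical management of individual patients.
#'
#' @param cases A case-record data frame.
#' @param coef A coefficient set (see [msi_coefficients()]).
#' @return `msi_probability()`: numeric vector in (0, 1). `add_msi()`: the
#'   input tibble with `severity_score` and `msi` appended.
#' @examples
#' rec <- as_case_records(data.frame(shock = 1, died = 0))
#' msi_probability(rec)
#' @export
msi_probability <- function(cases, coef = msi_coefficients()) {
  x <- derive_covariates(cases)
  logit <- coef[["beta0"]] +
    x$x1 * coef[["beta1"]] + x$x2 * coef[["beta2"]] + x$x3 * coef[["beta3"]] +
    x$x4 * coef[["beta4"]] + x$x5 * coef[["beta5"]] + x$x6 * coef[["beta6"]] +
    x$x7 * coef[["beta7"]]
  stats::plogis(logit)
}

#' @rdname msi_probability
#' @export
add_msi <- function(cases, coef = msi_coefficients()) {
  dplyr::mutate(tibble::as_tibble(cases),
                severity_score = severity_score(cases),
                msi = msi_probability(cases, coef))
}
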