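#' Read a case-record CSV
#'
#' Reads a line-listing of obstetric cases in the documented schema (see
#' [as_case_records()] for the column dictionary) and returns validated,
#' normalized case records. Raw laboratory columns are materialized into
#' their markers; rows that fail validation are reported with their row
#' numbers.
#'
#' @param path CSV path.
#' @param warn_unknown Warn on unrecognized columns.
#' @return A case-record tibble.
#' @export
read_cases <- function(path, warn_unknown = TRUE) {
  if (!file.exists(path)) stop("No such file: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0L) {
    warning("File has a header but zero data rows: ", path, call. = FALSE)
  }
  as_case_records(df, warn_unknown = warn_unknown)
}

#' Write case records to CSV
#'
#' Writes the standard case-record CSV (markers as 0/1, flags and outcome as
#' 0/1). A read-back with [read_cases()] reproduces the records.
#'
#' @param cases A case-record tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cases <- function(cases, path) {
  out <- tibble::as_tibble(cases)
  logi <- vapply(out, is.logical, logical(1))
  out[logi] <- lapply(out[logi], as.integer)
  readr::write_csv(out, path)
  invisible(path)
}

#' Write an analysis report
#'
#' Serializes any of the package's tabular results (accuracy statistics,
#' marker tables, score-mortality tables, benchmark reports) to JSON (full
#' numeric precision), CSV, or a human-readable text table with
#' display rounding. JSON and CSV keep stable field ordering, so re-runs
#' diff cleanly.
#'
#' @param report A data frame, or a named list of data frames/values.
#' @param path Output path.
#' @param format One of `"json"`, `"csv"`, `"txt"`.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv", "txt")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else if (format == "csv") {
    if (!is.data.frame(report)) {
      stop("CSV output needs a single data frame.", call. = FALSE)
    }
    readr::write_csv(report, path)
  } else {
    txt <- render_text_report(report)
    writeLines(txt, path)
  }
  invisible(path)
}

render_text_report <- function(report) {
  if (is.data.frame(report) && "statistic" %in% names(report) &&
      all(c("point", "lo", "hi") %in% names(report))) {
    # accuracy-table layout: estimator, point (95% CI)
    fmt <- function(stat, point, lo, hi) {
      digits <- if (stat %in% c("plr", "nlr")) 1 else 2
      ci <- if (is.na(lo)) "" else sprintf(" (%s-%s)",
                                           format(round(lo, digits + 1)),
                                           format(round(hi, digits + 1)))
      sprintf("%-28s %s%s",
              c(sensitivity = "Sensitivity",
                specificity = "Specificity",
                plr = "Positive likelihood ratio",
                nlr = "Negative likelihood ratio")[stat] %||% stat,
              if (is.na(point)) "undefined" else format(round(point, digits)),
              ci)
    }
    lines <- purrr::pmap_chr(report[c("statistic", "point", "lo", "hi")],
                             function(statistic, point, lo, hi) {
                               fmt(statistic, point, lo, hi)
                             })
    return(c("Accuracy of the WHO severity markers", "", lines, "",
             msi_caveat()))
  }
  if (is.data.frame(report)) {
    df <- report
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) round(x, 4))
    return(c(utils::capture.output(print(as.data.frame(df),
                                         row.names = FALSE)), "",
             msi_caveat()))
  }
  c(utils::capture.output(utils::str(report)), "", msi_caveat())
}

msi_caveat <- function() {
  paste("Note: MSI estimates benchmark services; they must not directly",
        "guide the management of critically ill patients.")
}
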