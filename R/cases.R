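#' Normalize a line-listing of obstetric case records
#'
#' Validates and normalizes a data frame of case records into the standard
#' layout used throughout the package: one row per woman, one logical column
#' per WHO severity marker (see [who_marker_catalog()]), logical covariate
#' flags and the vital-status outcome.
#'
#' Recognized columns:
#' * `case_id` (character; generated if absent),
#' * the 25 marker columns named by `marker_id` (0/1, logical, or
#'   `"true"/"false"/"yes"/"no"` case-insensitive; absent columns are filled
#'   with `FALSE`),
#' * flags `early_identification` (any life-threatening condition identified
#'   within the first 24 h of hospital stay), `severe_preeclampsia`, `cancer`
#'   (default `FALSE`),
#' * `died` (mandatory),
#' * optional raw laboratory columns (`creatinine_umol_l`, `creatinine_mg_dl`,
#'   `ph`, `lactate_mmol_l`, `platelets_per_ul`, `platelets_x10e9_per_l`,
#'   `bilirubin_umol_l`, `bilirubin_mg_dl`, `pao2_fio2_mmhg`,
#'   `respiratory_rate_per_min`, `spo2_low_duration_min`), which are
#'   materialized into their markers via [evaluate_lab_marker()]. An explicit
#'   non-missing marker column takes precedence over a lab-derived value; raw
#'   labs fill in only where the marker column is absent or `NA`.
#' * optional stratum labels (e.g. `facility`, `period`), carried through.
#'
#' Unknown columns are kept but reported with a warning so that typos in
#' marker names do not silently drop data.
#'
#' @param df A data frame of case records.
#' @param warn_unknown Warn about unrecognized columns (default `TRUE`).
#' @return A tibble with `case_id`, all 25 marker columns (logical), the three
#'   flags and `died`, plus any pass-through columns.
#' @export
as_case_records <- function(df, warn_unknown = TRUE) {
  stopifnot(is.data.frame(df))
  df <- tibble::as_tibble(df)
  ids <- marker_ids()
  if (!"died" %in% names(df)) {
    stop("Case records must contain a `died` column.", call. = FALSE)
  }
  if (!"case_id" %in% names(df)) {
    df$case_id <- sprintf("case_%05d", seq_len(nrow(df)))
  }
  df$case_id <- as.character(df$case_id)

  flag_cols <- c("early_identification", "severe_preeclampsia", "cancer")
  lab_map <- raw_lab_columns()
  known <- c("case_id", ids, flag_cols, "died", lab_map$column,
             "facility", "period", "stratum")
  unknown <- setdiff(names(df), known)
  if (warn_unknown && length(unknown) > 0L) {
    warning("Ignoring unrecognized column(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }

  explicit <- intersect(ids, names(df))
  for (col in c(explicit, intersect(c(flag_cols, "died"), names(df)))) {
    df[[col]] <- parse_bool(df[[col]], col)
  }
  for (col in setdiff(ids, explicit)) df[[col]] <- FALSE
  for (col in setdiff(flag_cols, names(df))) df[[col]] <- FALSE
  if (anyNA(df$died)) {
    stop("`died` contains missing values; vital status at discharge is mandatory.",
         call. = FALSE)
  }

  # materialize raw labs into marker columns where the marker is not
  # explicitly recorded
  for (i in seq_len(nrow(lab_map))) {
    col <- lab_map$column[i]
    if (!col %in% names(df)) next
    vals <- df[[col]]
    if (!is.numeric(vals)) vals <- suppressWarnings(as.numeric(vals))
    if (any(vals < 0, na.rm = TRUE)) {
      stop("Negative values in lab column `", col, "` (rows ",
           paste(which(vals < 0), collapse = ", "), ").", call. = FALSE)
    }
    marker <- lab_map$marker_id[i]
    derived <- !is.na(vals) &
      evaluate_lab_marker(lab_map$analyte[i], ifelse(is.na(vals), 0, vals),
                          lab_map$unit[i])
    use_lab <- if (marker %in% explicit) is.na(df[[marker]]) else rep(TRUE, nrow(df))
    df[[marker]] <- ifelse(use_lab, df[[marker]] %in% TRUE | derived,
                           df[[marker]])
  }
  for (col in ids) df[[col]][is.na(df[[col]])] <- FALSE

  dplyr::relocate(df, "case_id", dplyr::all_of(ids), dplyr::all_of(flag_cols),
                  "died")
}

# map from raw-lab CSV column to (analyte, unit, marker)
raw_lab_columns <- function() {
  tibble::tribble(
    ~column,                    ~analyte,           ~unit,         ~marker_id,
    "creatinine_umol_l",        "creatinine",       "umol/l",      "creatinine_high",
    "creatinine_mg_dl",         "creatinine",       "mg/dl",       "creatinine_high",
    "ph",                       "ph",               "unitless",    "ph_low",
    "lactate_mmol_l",           "lactate",          "mmol/l",      "lactate_high",
    "platelets_per_ul",         "platelets",        "per_ul",      "thrombocytopenia",
    "platelets_x10e9_per_l",    "platelets",        "x10e9_per_l", "thrombocytopenia",
    "bilirubin_umol_l",         "bilirubin",        "umol/l",      "bilirubin_high",
    "bilirubin_mg_dl",          "bilirubin",        "mg/dl",       "bilirubin_high",
    "pao2_fio2_mmhg",           "pao2_fio2",        "mmhg",        "pao2_fio2_low",
    "respiratory_rate_per_min", "respiratory_rate", "per_min",     "resp_rate_extreme",
    "spo2_low_duration_min",    "spo2_duration",    "min",         "spo2_low"
  )
}

parse_bool <- function(x, col) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    bad <- !is.na(x) & !x %in% c(0, 1)
    if (any(bad)) {
      stop("Column `", col, "`: numeric values must be 0 or 1 (rows ",
           paste(utils::head(which(bad), 5), collapse = ", "), ").",
           call. = FALSE)
    }
    return(x == 1)
  }
  x_chr <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x_chr))
  out[x_chr %in% c("1", "true", "yes")] <- TRUE
  out[x_chr %in% c("0", "false", "no")] <- FALSE
  bad <- !is.na(x_chr) & x_chr != "" & is.na(out)
  if (any(bad)) {
    stop("Column `", col, "`: unparseable boolean value(s) ",
         paste(unique(x_chr[bad]), collapse = ", "),
         " (accepted: 0, 1, true, false, yes, no).", call. = FALSE)
  }
  out
}

#' Maternal severity score
#'
#' The maternal severity score of a case is the number of distinct WHO
#' severity markers present (0 to 25).
#'
#' @param cases A case-record data frame (see [as_case_records()]).
#' @return Integer vector, one score per row.
#' @export
severity_score <- function(cases) {
  ids <- marker_ids()
  missing <- setdiff(ids, names(cases))
  if (length(missing) > 0L) {
    stop("Case records lack marker column(s): ",
         paste(missing, collapse = ", "),
         ". Run as_case_records() first.", call. = FALSE)
  }
  m <- as.matrix(dplyr::mutate(cases[ids], dplyr::across(dplyr::everything(),
                                                         ~ .x %in% TRUE)))
  as.integer(rowSums(m))
}

#' Classify cases into WHO maternal near-miss categories
#'
#' Adds the maternal severity score and the WHO outcome category to a cohort:
#' a woman who died is a `maternal_death`; a survivor with at least one
#' life-threatening condition is a `maternal_near_miss`; all other women have
#' `no_life_threatening_condition`. The three categories are mutually
#' exclusive and exhaustive.
#'
#' A death without any recorded marker is accepted and classified as a
#' maternal death, but flagged with a warning: in validated surveillance data
#' every woman who died presented at least one life-threatening condition.
#'
#' @param cases A case-record data frame (see [as_case_records()]).
#' @return The input tibble with columns `severity_score` (integer) and
#'   `category` (factor with the three levels above) appended.
#' @examples
#' cohort <- as_case_records(data.frame(shock = c(1, 0), died = c(0, 0)))
#' classify_cases(cohort)
#' @export
classify_cases <- function(cases) {
  score <- severity_score(cases)
  died <- parse_bool(cases$died, "died")
  n_flag <- sum(died & score == 0L)
  if (n_flag > 0L) {
    warning(n_flag, " death(s) without any recorded severity marker; ",
            "classified as maternal_death but review the source records.",
            call. = FALSE)
  }
  category <- factor(
    dplyr::case_when(
      died ~ "maternal_death",
      score > 0L ~ "maternal_near_miss",
      TRUE ~ "no_life_threatening_condition"
    ),
    levels = c("maternal_death", "maternal_near_miss",
               "no_life_threatening_condition")
  )
  dplyr::mutate(tibble::as_tibble(cases), severity_score = score,
                category = category)
}

#' Organ-dysfunction profile
#'
#' Summarizes, per case and organ system, the highest severity stratum
#' present: `groupB` dominates `groupA_only`, which dominates `none`.
#'
#' @param cases A case-record data frame.
#' @return A long tibble with columns `case_id`, `organ_system` and `level`
#'   (factor: `none < groupA_only < groupB`), seven rows per case.
#' @export
organ_profile <- function(cases) {
  catalog <- who_marker_catalog()
  long <- tidyr::pivot_longer(
    dplyr::mutate(cases[, c("case_id", marker_ids())],
                  dplyr::across(-"case_id", ~ .x %in% TRUE)),
    -"case_id", names_to = "marker_id", values_to = "present"
  )
  long <- dplyr::left_join(long, catalog[, c("marker_id", "organ_system", "group")],
                           by = "marker_id")
  prof <- dplyr::summarise(
    dplyr::group_by(long, .data$case_id, .data$organ_system),
    level = if (any(.data$present & .data$group == "B")) "groupB"
            else if (any(.data$present)) "groupA_only" else "none",
    .groups = "drop"
  )
  prof$level <- factor(prof$level, levels = c("none", "groupA_only", "groupB"),
                       ordered = TRUE)
  # keep the original case order
  prof[order(match(prof$case_id, cases$case_id)), ]
}
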