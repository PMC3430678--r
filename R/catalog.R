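#' The WHO severity-marker catalog
#'
#' Returns the 25 WHO life-threatening conditions (severity markers) used in
#' maternal near-miss assessments, one row per marker. Markers are grouped by
#' organ system and stratified into group A and group B; group B reflects SOFA
#' score categories 3 and 4, i.e. markers of greater severity.
#'
#' Lab-threshold markers carry the diagnostic cutoff in up to two unit scales
#' (e.g. creatinine >= 300 umol/l or >= 3.5 mg/dl). The published catalog
#' prints "mmol/l" for creatinine and bilirubin; those magnitudes are only
#' physiologically coherent as umol/l, so the SI scale is stored as umol/l
#' while keeping the printed cutoff values verbatim.
#'
#' @return A tibble with 25 rows and columns `marker_id`, `label`,
#'   `organ_system`, `group` (`"A"` or `"B"`), `kind` (`"clinical_sign"`,
#'   `"lab_threshold"` or `"management_proxy"`).
#' @examples
#' who_marker_catalog()
#' @export
who_marker_catalog <- function() {
  tibble::tribble(
    ~marker_id,             ~label,                                                   ~organ_system,               ~group, ~kind,
    "shock",                "Shock",                                                  "cardiovascular",            "A",    "clinical_sign",
    "lactate_high",         "Lactate >5 mmol/l",                                      "cardiovascular",            "A",    "lab_threshold",
    "ph_low",               "pH <7.1",                                                "cardiovascular",            "B",    "lab_threshold",
    "vasoactive_drugs",     "Use of continuous vasoactive drugs",                     "cardiovascular",            "B",    "management_proxy",
    "cardiac_arrest",       "Cardiac arrest",                                         "cardiovascular",            "B",    "clinical_sign",
    "cpr",                  "Cardio-pulmonary resuscitation (CPR)",                   "cardiovascular",            "B",    "management_proxy",
    "acute_cyanosis",       "Acute cyanosis",                                         "respiratory",               "A",    "clinical_sign",
    "resp_rate_extreme",    "Respiratory rate >40 or <6/min",                         "respiratory",               "A",    "lab_threshold",
    "spo2_low",             "Oxygen saturation <90% for >=60 minutes",                "respiratory",               "A",    "lab_threshold",
    "gasping",              "Gasping",                                                "respiratory",               "B",    "clinical_sign",
    "pao2_fio2_low",        "PaO2/FiO2 <200 mmHg",                                    "respiratory",               "B",    "lab_threshold",
    "intubation",           "Intubation and ventilation not related to anesthesia",   "respiratory",               "B",    "management_proxy",
    "oliguria",             "Oliguria non responsive to fluids or diuretics",         "renal",                     "A",    "clinical_sign",
    "creatinine_high",      "Creatinine >=300 umol/l or >=3.5 mg/dl",                 "renal",                     "B",    "lab_threshold",
    "dialysis",             "Dialysis for acute renal failure",                       "renal",                     "B",    "management_proxy",
    "clotting_failure",     "Clotting failure",                                       "coagulation/hematological", "A",    "clinical_sign",
    "transfusion",          "Transfusion of >=5 units of blood/red cells",            "coagulation/hematological", "A",    "management_proxy",
    "thrombocytopenia",     "Acute thrombocytopenia (<50 000 platelets)",             "coagulation/hematological", "B",    "lab_threshold",
    "jaundice_preeclampsia","Jaundice in the presence of pre-eclampsia",              "hepatic",                   "A",    "clinical_sign",
    "bilirubin_high",       "Bilirubin >100 umol/l or >6.0 mg/dl",                    "hepatic",                   "B",    "lab_threshold",
    "metabolic_coma",       "Metabolic coma",                                         "neurological",              "A",    "clinical_sign",
    "stroke",               "Stroke",                                                 "neurological",              "A",    "clinical_sign",
    "status_epilepticus",   "Status epilepticus/uncontrollable fits/total paralysis", "neurological",              "A",    "clinical_sign",
    "coma_12h",             "Coma/loss of consciousness lasting >=12 hours",          "neurological",              "B",    "clinical_sign",
    "hysterectomy",         "Hysterectomy due to infection or hemorrhage",            "uterine",                   "A",    "management_proxy"
  )
}

#' @rdname who_marker_catalog
#' @format NULL
#' @export
marker_ids <- function() who_marker_catalog()$marker_id

# Marker groups feeding the MSI cardiovascular- and respiratory-failure
# covariates (x5, x6): the group B markers of those two organ systems.
cardiovascular_failure_markers <- c("ph_low", "vasoactive_drugs", "cardiac_arrest", "cpr")
respiratory_failure_markers <- c("gasping", "pao2_fio2_low", "intubation")

# Lab thresholds behind the threshold-bearing markers. `direction` is applied
# with the printed strictness: "ge"/"le" non-strict, "gt"/"lt" strict.
# `respiratory_rate` is out of range when >40 OR <6; `spo2_duration` is the
# time (minutes) spent below 90% saturation.
lab_threshold_table <- function() {
  tibble::tribble(
    ~analyte,            ~unit,          ~cutoff, ~direction, ~marker_id,
    "ph",                "unitless",     7.1,     "lt",       "ph_low",
    "lactate",           "mmol/l",       5,       "gt",       "lactate_high",
    "respiratory_rate",  "per_min",      40,      "gt",       "resp_rate_extreme",
    "respiratory_rate",  "per_min",      6,       "lt",       "resp_rate_extreme",
    "spo2_duration",     "min",          60,      "ge",       "spo2_low",
    "pao2_fio2",         "mmhg",         200,     "lt",       "pao2_fio2_low",
    "creatinine",        "umol/l",       300,     "ge",       "creatinine_high",
    "creatinine",        "mg/dl",        3.5,     "ge",       "creatinine_high",
    "platelets",         "per_ul",       50000,   "lt",       "thrombocytopenia",
    "platelets",         "x10e9_per_l",  50,      "lt",       "thrombocytopenia",
    "bilirubin",         "umol/l",       100,     "gt",       "bilirubin_high",
    "bilirubin",         "mg/dl",        6.0,     "gt",       "bilirubin_high"
  )
}

#' Evaluate a laboratory value against its WHO marker threshold
#'
#' Tests whether a raw laboratory or physiological value crosses the
#' diagnostic cutoff of the corresponding severity marker, honouring the
#' printed inequality direction and strictness (e.g. creatinine ">= 3.5
#' mg/dl" is non-strict, thrombocytopenia "< 50 000 platelets" is strict).
#' Dual-unit markers accept either unit scale with its own printed cutoff.
#'
#' @param analyte One of `"ph"`, `"lactate"`, `"respiratory_rate"`,
#'   `"spo2_duration"` (minutes with oxygen saturation below 90%),
#'   `"pao2_fio2"`, `"creatinine"`, `"platelets"`, `"bilirubin"`.
#' @param value Numeric measurement (vectorised).
#' @param unit Unit string; must be one of the recognized units for the
#'   analyte. Unknown analytes or units are an error, never coerced.
#' @return Logical vector: `TRUE` where the value crosses the cutoff.
#' @examples
#' evaluate_lab_marker("creatinine", 3.5, "mg/dl")    # TRUE (>= 3.5)
#' evaluate_lab_marker("platelets", 50000, "per_ul")  # FALSE (strict <)
#' evaluate_lab_marker("ph", c(7.10, 7.09), "unitless")
#' @export
evaluate_lab_marker <- function(analyte, value, unit) {
  stopifnot(is.character(analyte), length(analyte) == 1L,
            is.character(unit), length(unit) == 1L)
  thr <- lab_threshold_table()
  if (!analyte %in% thr$analyte) {
    stop("Unknown analyte '", analyte, "'. Recognized analytes: ",
         paste(unique(thr$analyte), collapse = ", "), call. = FALSE)
  }
  rows <- thr[thr$analyte == analyte & thr$unit == unit, ]
  if (nrow(rows) == 0L) {
    stop("Unknown unit '", unit, "' for analyte '", analyte,
         "'. Recognized units: ",
         paste(thr$unit[thr$analyte == analyte], collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(value)) stop("`value` must be numeric.", call. = FALSE)
  if (any(value < 0, na.rm = TRUE) && analyte != "ph") {
    stop("Negative value for analyte '", analyte, "'.", call. = FALSE)
  }
  out <- rep(FALSE, length(value))
  for (i in seq_len(nrow(rows))) {
    hit <- switch(rows$direction[i],
                  ge = value >= rows$cutoff[i],
                  gt = value > rows$cutoff[i],
                  le = value <= rows$cutoff[i],
                  lt = value < rows$cutoff[i])
    out <- out | hit
  }
  out
}

#' Export the marker catalog as JSON
#'
#' Serializes the full catalog, including lab thresholds, to a JSON file for
#' audit or for use by external tooling.
#'
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_marker_catalog_json <- function(path) {
  obj <- list(
    markers = who_marker_catalog(),
    lab_thresholds = lab_threshold_table(),
    cardiovascular_failure_markers = cardiovascular_failure_markers,
    respiratory_failure_markers = respiratory_failure_markers
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
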