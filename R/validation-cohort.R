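#' Published summary counts of the MSI validation cohort
#'
#' The `"souza2012"` MSI coefficients were estimated in a one-year
#' prospective surveillance of 27 Brazilian referral maternity hospitals
#' (2009--2010): 82,388 deliveries, 82,144 live births, 9,555 women with
#' pregnancy-related complications, of whom 910 presented at least one WHO
#' life-threatening condition — 140 maternal deaths and 770 maternal near
#' misses. This function returns the published summary counts of that cohort,
#' which serve three purposes: reconstructing the published accuracy and
#' risk statistics from first principles, spot-checking the package's
#' estimators, and calibrating the synthetic cohort generator.
#'
#' @return A list of tibbles/values:
#' \describe{
#'   \item{denominators}{`deliveries`, `live_births`, `complications`,
#'     `severe_cases`, `maternal_deaths`, `near_misses`.}
#'   \item{two_by_two}{The accuracy 2x2 counts of criterion positivity
#'     against death, in the all-women and complications-only populations.}
#'   \item{marker_counts}{Per marker: deaths and survivors among cases
#'     presenting it (complication cohort).}
#'   \item{score_distribution}{Cases and deaths by severity score
#'     (0 ... 14, 15+) within the complication cohort.}
#' }
#' @export
validation_cohort_counts <- function() {
  denominators <- tibble::tibble(
    deliveries = 82388, live_births = 82144, complications = 9555,
    severe_cases = 910, maternal_deaths = 140, near_misses = 770
  )
  two_by_two <- tibble::tribble(
    ~population,      ~tp,  ~fp,  ~fn, ~tn,
    "all_women",      140L, 770L, 0L,  81478L,
    "complications",  140L, 770L, 0L,  8645L
  )
  marker_counts <- tibble::tribble(
    ~marker_id,              ~deaths, ~survivors,
    "shock",                 74L,     176L,
    "cardiac_arrest",        51L,     13L,
    "ph_low",                51L,     22L,
    "lactate_high",          24L,     56L,
    "vasoactive_drugs",      101L,    143L,
    "cpr",                   102L,    18L,
    "acute_cyanosis",        55L,     68L,
    "gasping",               24L,     13L,
    "resp_rate_extreme",     74L,     118L,
    "spo2_low",              80L,     106L,
    "pao2_fio2_low",         53L,     48L,
    "intubation",            123L,    172L,
    "oliguria",              35L,     55L,
    "creatinine_high",       21L,     77L,
    "dialysis",              24L,     39L,
    "clotting_failure",      33L,     63L,
    "thrombocytopenia",      30L,     170L,
    "transfusion",           50L,     199L,
    "jaundice_preeclampsia", 7L,      22L,
    "bilirubin_high",        13L,     37L,
    "coma_12h",              36L,     29L,
    "metabolic_coma",        6L,      12L,
    "stroke",                10L,     15L,
    "status_epilepticus",    5L,      11L,
    "hysterectomy",          22L,     149L
  )
  score_distribution <- tibble::tibble(
    score = 0:15, # 15 is the open "15+" category
    n = c(8645L, 402L, 148L, 70L, 61L, 59L, 46L, 29L, 18L, 20L, 20L, 6L,
          13L, 4L, 7L, 7L),
    deaths = c(0L, 0L, 3L, 6L, 14L, 19L, 16L, 15L, 10L, 15L, 13L, 4L, 11L,
               3L, 5L, 6L)
  )
  list(denominators = denominators, two_by_two = two_by_two,
       marker_counts = marker_counts, score_distribution = score_distribution)
}
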