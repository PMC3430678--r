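# build a case-record tibble from compact marker specifications
make_cases <- function(markers = list(character(0)), died = FALSE,
                       early_identification = FALSE,
                       severe_preeclampsia = FALSE, cancer = FALSE, ...) {
  n <- length(markers)
  df <- tibble::as_tibble(stats::setNames(
    lapply(marker_ids(), function(id) {
      vapply(markers, function(m) id %in% m, logical(1))
    }), marker_ids()))
  df$died <- rep_len(died, n)
  df$early_identification <- rep_len(early_identification, n)
  df$severe_preeclampsia <- rep_len(severe_preeclampsia, n)
  df$cancer <- rep_len(cancer, n)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  as_case_records(df, warn_unknown = FALSE)
}

# expand per-score-bin counts into a case-level cohort (markers chosen
# arbitrarily to hit the requested score)
cohort_from_score_distribution <- function(score, n, deaths) {
  ids <- marker_ids()
  rows <- purrr::pmap(list(score, n, deaths), function(s, nn, dd) {
    mk <- ids[seq_len(min(s, length(ids)))]
    make_cases(markers = rep(list(mk), nn),
               died = c(rep(TRUE, dd), rep(FALSE, nn - dd)))
  })
  dplyr::bind_rows(rows)
}
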