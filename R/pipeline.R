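# End-to-end scoring pipeline over a cohort, plus flat-file emitters.

#' Run the full scoring pipeline on a cohort
#'
#' Screens candidates (DKA discharge coding combined with FRIII-treated
#' episodes), ascertains DKA windows, scores adherence, detects
#' complications and computes outcomes, restricted to the screened
#' candidates.
#'
#' @param cohort A `dka_cohort`.
#' @param thresholds A [dka_thresholds()] object.
#' @param schedule A [fluid_schedule()].
#' @return A list of class `dka_scores` with tibbles `windows`, `adherence`,
#'   `complications`, `outcomes` and the character vector `candidates`.
#' @export
#' @examples
#' sim <- generate_cohort(sim_config(
#'   seed = 1,
#'   hospitals = data.frame(code = "A", onboard_quarter = "2022-Q1",
#'                          episodes_per_quarter = 5, poisson = FALSE),
#'   end_quarter = "2022-Q2"
#' ))
#' scores <- dka_pipeline(sim$cohort)
#' scores$adherence
dka_pipeline <- function(cohort, thresholds = dka_thresholds(),
                         schedule = fluid_schedule()) {
  validate_dka_cohort(cohort)
  candidates <- screen_candidates(cohort$discharge_codes,
                                  frii_treated_codes(cohort))
  sub <- cohort
  sub$episodes <- cohort$episodes[cohort$episodes$episode_code %in% candidates, ]
  sub$observations <-
    cohort$observations[cohort$observations$episode_code %in% candidates, ]
  sub$prescriptions <-
    cohort$prescriptions[cohort$prescriptions$episode_code %in% candidates, ]
  windows <- ascertain_windows(sub, thresholds)
  structure(
    list(
      candidates = candidates,
      windows = windows,
      adherence = score_adherence(sub, windows, thresholds, schedule),
      complications = complication_flags(sub, windows, thresholds),
      outcomes = outcome_records(sub, windows)
    ),
    class = "dka_scores"
  )
}

#' @export
print.dka_scores <- function(x, ...) {
  cat("<dka_scores>\n")
  cat(sprintf("  %d candidate episodes; %d diagnosed, %d resolved\n",
              length(x$candidates),
              sum(!is.na(x$windows$diagnosis_time)),
              sum(x$windows$resolved)))
  for (ind in c("frii", "fluid", "glucose", "ketone")) {
    flag <- x$adherence[[paste0(ind, "_in_band")]]
    cat(sprintf("  %-7s in band: %d/%d\n", ind, sum(flag, na.rm = TRUE),
                sum(!is.na(flag))))
  }
  invisible(x)
}

#' Write pipeline outputs to CSV
#'
#' Emits `windows.csv`, `adherence.csv` (percentages to one decimal),
#' `complications.csv` and `outcomes.csv`.
#'
#' @param scores A `dka_scores` list from [dka_pipeline()].
#' @param directory Output directory (created if absent).
#' @return Named character vector of file paths, invisibly.
#' @export
write_scores <- function(scores, directory) {
  if (!dir.exists(directory)) {
    dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  }
  w <- scores$windows
  windows_out <- tibble::tibble(
    episode_code = w$episode_code,
    diagnosis_time = .format_minute(w$diagnosis_time),
    resolution_time = .format_minute(w$resolution_time),
    resolved = .fmt_bool(w$resolved),
    dka_duration_h = round(w$dka_duration_h, 2)
  )
  a <- scores$adherence
  adherence_out <- tibble::tibble(
    episode_code = a$episode_code,
    frii_pct = round(a$frii_pct, 1), fluid_pct = round(a$fluid_pct, 1),
    glucose_pct = round(a$glucose_pct, 1), ketone_pct = round(a$ketone_pct, 1),
    frii_in_band = .fmt_bool(a$frii_in_band),
    fluid_in_band = .fmt_bool(a$fluid_in_band),
    glucose_in_band = .fmt_bool(a$glucose_in_band),
    ketone_in_band = .fmt_bool(a$ketone_in_band)
  )
  cmpl <- scores$complications
  complications_out <- tibble::tibble(
    episode_code = cmpl$episode_code,
    hypoglycaemia = .fmt_bool(cmpl$hypoglycaemia),
    hypokalaemia = .fmt_bool(cmpl$hypokalaemia),
    hyperkalaemia = .fmt_bool(cmpl$hyperkalaemia)
  )
  o <- scores$outcomes
  outcomes_out <- tibble::tibble(
    episode_code = o$episode_code,
    dka_duration_h = round(o$dka_duration_h, 2),
    length_of_stay_d = round(o$length_of_stay_d, 2)
  )
  paths <- c(
    windows = file.path(directory, "windows.csv"),
    adherence = file.path(directory, "adherence.csv"),
    complications = file.path(directory, "complications.csv"),
    outcomes = file.path(directory, "outcomes.csv")
  )
  readr::write_csv(windows_out, paths[["windows"]], progress = FALSE)
  readr::write_csv(adherence_out, paths[["adherence"]], progress = FALSE)
  readr::write_csv(complications_out, paths[["complications"]], progress = FALSE)
  readr::write_csv(outcomes_out, paths[["outcomes"]], progress = FALSE)
  invisible(paths)
}
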