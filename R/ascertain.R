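# Case ascertainment: screening by discharge coding / insulin-infusion
# treatment, JBDS-IP diagnosis and resolution detection, DKA duration.

#' Screen candidate DKA episodes
#'
#' Returns the union of episodes carrying a DKA discharge code (the E10-E14
#' coma/ketoacidosis ICD-10 list, [dka_icd10_codes()]) and episodes treated
#' with a fixed-rate insulin infusion. The second arm catches admissions the
#' coding department missed.
#'
#' @param codes Tibble with `episode_code` and `icd10` columns.
#' @param frii_treated Character vector of episode codes treated with FRIII
#'   (see [frii_treated_codes()]).
#' @param code_list ICD-10 codes regarded as DKA.
#' @return Sorted character vector of unique candidate episode codes.
#' @export
#' @examples
#' screen_candidates(
#'   tibble::tibble(episode_code = c("ep1", "ep3"), icd10 = c("E10.1", "I21.0")),
#'   frii_treated = "ep2"
#' )
screen_candidates <- function(codes, frii_treated = character(),
                              code_list = dka_icd10_codes()) {
  coded <- codes$episode_code[codes$icd10 %in% code_list]
  sort(unique(c(coded, frii_treated)))
}

#' Episodes treated with a fixed-rate insulin infusion
#'
#' @param cohort A `dka_cohort`.
#' @return Character vector of episode codes with at least one FRIII
#'   prescription.
#' @export
frii_treated_codes <- function(cohort) {
  unique(cohort$prescriptions$episode_code[cohort$prescriptions$kind == "frii"])
}

# Most recent value of one analyte at or before `at`, ignoring readings older
# than the staleness lookback. Ties at the same timestamp resolve to the first
# reading in file order.
.latest_value <- function(times, values, at, lookback_h) {
  if (length(times) == 0L) return(NA_real_)
  tn <- as.numeric(times)
  atn <- as.numeric(at)
  i <- findInterval(atn, tn)
  if (i == 0L) return(NA_real_)
  if (atn - tn[i] > lookback_h * 3600) return(NA_real_)
  values[match(tn[i], tn)]
}

.obs_split <- function(obs) {
  lapply(stats::setNames(.ANALYTES, .ANALYTES), function(a) {
    sel <- obs$analyte == a
    list(t = obs$timestamp[sel], v = obs$value[sel])
  })
}

#' Evaluate the DKA diagnostic criteria at a time point
#'
#' Applies the composite JBDS-IP diagnosis rule at time `at`, using the most
#' recent reading of each analyte within the staleness lookback:
#' (glucose > 11 mmol/L OR known diabetes) AND (blood ketones > 3 mmol/L OR
#' urine ketones at least ++) AND (pH < 7.30 OR bicarbonate < 15 mmol/L),
#' thresholds taken from `thresholds`. Returns `NA` (indeterminate, distinct
#' from `FALSE`) when no ketone datum or no acid-base datum is available,
#' unless another arm already fails determinately.
#'
#' @param obs One episode's observations tibble (`timestamp`, `analyte`,
#'   `value`), sorted by timestamp.
#' @param at Evaluation time (`POSIXct`).
#' @param has_history Known history of diabetes (substitutes for the glucose
#'   arm).
#' @param urine_ketones Urine ketones at least ++ (substitutes for the blood
#'   ketone arm of diagnosis only).
#' @param thresholds A [dka_thresholds()] object.
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
meets_dka_criteria <- function(obs, at, has_history = FALSE,
                               urine_ketones = FALSE,
                               thresholds = dka_thresholds()) {
  sp <- .obs_split(obs)
  lb <- thresholds$lookback_h
  g <- .latest_value(sp$glucose$t, sp$glucose$v, at, lb)
  k <- .latest_value(sp$ketones$t, sp$ketones$v, at, lb)
  ph <- .latest_value(sp$ph$t, sp$ph$v, at, lb)
  bic <- .latest_value(sp$bicarbonate$t, sp$bicarbonate$v, at, lb)

  glucose_arm <- isTRUE(has_history) ||
    (!is.na(g) && g > thresholds$dka_glucose)
  ketone_arm <- if (isTRUE(urine_ketones)) TRUE else k > thresholds$dka_ketones
  acid_arm <- if (is.na(ph) && is.na(bic)) {
    NA
  } else {
    isTRUE(ph < thresholds$dka_ph) || isTRUE(bic < thresholds$dka_bicarbonate)
  }
  glucose_arm & ketone_arm & acid_arm
}

#' Detect the DKA diagnosis time
#'
#' Scans an episode's observation timestamps in order and returns the
#' earliest at which [meets_dka_criteria()] is `TRUE`; `NA` if the criteria
#' are never met. An episode with no observations returns `NA` with a
#' warning.
#'
#' @inheritParams meets_dka_criteria
#' @return A `POSIXct` timestamp, or `NA`.
#' @export
detect_diagnosis <- function(obs, has_history = FALSE, urine_ketones = FALSE,
                             thresholds = dka_thresholds()) {
  if (nrow(obs) == 0L) {
    rlang::warn("Episode has no observations; diagnosis indeterminate.",
                class = "dkaudit_no_observations")
    return(.na_time())
  }
  ts <- sort(unique(obs$timestamp))
  for (t in seq_along(ts)) {
    if (isTRUE(meets_dka_criteria(obs, ts[t], has_history, urine_ketones,
                                  thresholds))) {
      return(ts[t])
    }
  }
  .na_time()
}

# Composite resolution condition at one time point: (pH > res_ph OR
# bicarbonate > res_bicarbonate) AND blood ketones < res_ketones. Resolution
# always requires blood ketones; urine ketones play no part.
.resolution_holds <- function(sp, at, thresholds) {
  lb <- thresholds$lookback_h
  k <- .latest_value(sp$ketones$t, sp$ketones$v, at, lb)
  ph <- .latest_value(sp$ph$t, sp$ph$v, at, lb)
  bic <- .latest_value(sp$bicarbonate$t, sp$bicarbonate$v, at, lb)
  acid <- isTRUE(ph > thresholds$res_ph) ||
    isTRUE(bic > thresholds$res_bicarbonate)
  isTRUE(acid) && isTRUE(k < thresholds$res_ketones)
}

#' Detect the DKA resolution time
#'
#' The "sustained for two consecutive hours" rule is read as two reading
#' times, spaced `res_gap_min` +/- `res_gap_tol_min` minutes apart, at both
#' of which (pH > 7.30 OR bicarbonate > 18 mmol/L) AND blood ketones
#' < 0.6 mmol/L hold. The scan covers observation timestamps strictly after
#' `diagnosis_time` (up to `until`, if given); the earliest qualifying pair
#' wins and the resolution is stamped at its second reading (configurable via
#' `thresholds$res_mark`). Returns `NA` if biochemistry never normalises.
#'
#' @inheritParams meets_dka_criteria
#' @param diagnosis_time Diagnosis timestamp (see [detect_diagnosis()]).
#' @param until Optional scan end (e.g. discharge time).
#' @return A `POSIXct` timestamp, or `NA`.
#' @export
detect_resolution <- function(obs, diagnosis_time,
                              thresholds = dka_thresholds(), until = NULL) {
  ts <- sort(unique(obs$timestamp))
  ts <- ts[ts > diagnosis_time]
  if (!is.null(until)) ts <- ts[ts <= until]
  if (length(ts) == 0L) {
    rlang::warn("No observations after diagnosis time; resolution indeterminate.",
                class = "dkaudit_no_post_diagnosis")
    return(.na_time())
  }
  sp <- .obs_split(obs)
  ok <- vapply(ts, function(t) .resolution_holds(sp, t, thresholds), logical(1))
  qual <- as.numeric(ts[ok])
  if (length(qual) >= 2L) {
    lo <- (thresholds$res_gap_min - thresholds$res_gap_tol_min) * 60
    hi <- (thresholds$res_gap_min + thresholds$res_gap_tol_min) * 60
    for (j in 2:length(qual)) {
      gaps <- qual[j] - qual[seq_len(j - 1L)]
      hit <- which(gaps >= lo & gaps <= hi)
      if (length(hit) > 0L) {
        mark <- if (thresholds$res_mark == "second") qual[j] else qual[hit[1]]
        return(as.POSIXct(mark, origin = "1970-01-01", tz = "UTC"))
      }
    }
  }
  .na_time()
}

#' DKA duration in hours
#'
#' Time from diagnosis to resolution in fractional hours; `NA` for
#' unresolved windows.
#'
#' @param diagnosis_time,resolution_time `POSIXct` timestamps (vectorised).
#' @return Numeric hours (`NA` where unresolved).
#' @export
dka_duration_hours <- function(diagnosis_time, resolution_time) {
  as.numeric(difftime(resolution_time, diagnosis_time, units = "hours"))
}

#' Ascertain DKA windows for a whole cohort
#'
#' Runs [detect_diagnosis()] and [detect_resolution()] over every episode and
#' assembles the per-episode DKA windows. An episode's `confirmed` override
#' column, when non-missing, replaces the automatic adjudication: `FALSE`
#' forces the episode out (no window) regardless of biochemistry, `TRUE`
#' keeps it in whenever a diagnosis time exists.
#'
#' @param cohort A `dka_cohort`.
#' @param thresholds A [dka_thresholds()] object.
#' @return Tibble with `episode_code`, `diagnosis_time`, `resolution_time`,
#'   `resolved`, `dka_duration_h`.
#' @export
ascertain_windows <- function(cohort, thresholds = dka_thresholds()) {
  ep <- cohort$episodes
  obs_by <- split(cohort$observations, cohort$observations$episode_code)
  empty_obs <- cohort$observations[0, ]
  rows <- lapply(seq_len(nrow(ep)), function(i) {
    code <- ep$episode_code[i]
    obs <- obs_by[[code]] %||% empty_obs
    if (isFALSE(ep$confirmed[i])) {
      diag <- .na_time()
    } else {
      diag <- withCallingHandlers(
        detect_diagnosis(obs, ep$has_diabetes_history[i], ep$urine_ketones[i],
                         thresholds),
        dkaudit_no_observations = function(w) invokeRestart("muffleWarning")
      )
    }
    if (is.na(diag)) {
      res <- .na_time()
    } else {
      res <- withCallingHandlers(
        detect_resolution(obs, diag, thresholds, until = ep$discharge[i]),
        dkaudit_no_post_diagnosis = function(w) invokeRestart("muffleWarning")
      )
    }
    tibble::tibble(
      episode_code = code, diagnosis_time = diag, resolution_time = res,
      resolved = !is.na(res),
      dka_duration_h = dka_duration_hours(diag, res)
    )
  })
  dplyr::bind_rows(rows)
}
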