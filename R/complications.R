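# Treatment complications during the DKA window and outcome metrics.

#' Classify a potassium value
#'
#' Hypokalaemia below 3.5 mmol/L, normokalaemia from 3.5 to 5.5 mmol/L
#' (inclusive at both ends), hyperkalaemia above 5.5 mmol/L.
#'
#' @param value_mmol_l Potassium value(s), mmol/L; must be positive.
#' @param thresholds A [dka_thresholds()] object.
#' @return Character vector in `c("hypo", "normo", "hyper")`.
#' @export
#' @examples
#' classify_potassium(c(3.4, 5.5, 5.6))
classify_potassium <- function(value_mmol_l, thresholds = dka_thresholds()) {
  if (any(is.na(value_mmol_l) | value_mmol_l <= 0)) {
    .abort_domain("Potassium values must be positive.")
  }
  dplyr::case_when(
    value_mmol_l < thresholds$hypokalaemia ~ "hypo",
    value_mmol_l > thresholds$hyperkalaemia ~ "hyper",
    TRUE ~ "normo"
  )
}

#' Detect hypoglycaemia in a DKA window
#'
#' `TRUE` when any glucose reading strictly below the hypoglycaemia threshold
#' (4 mmol/L) falls inside the closed window from diagnosis to resolution (or
#' to `window_end`, typically discharge, for unresolved episodes).
#'
#' @param obs One episode's observations tibble.
#' @param diagnosis_time Window start (`POSIXct`).
#' @param window_end Window end: resolution time, or discharge if unresolved.
#' @param thresholds A [dka_thresholds()] object.
#' @return Logical scalar; `FALSE` with a warning when the window holds no
#'   glucose reading.
#' @export
detect_hypoglycaemia <- function(obs, diagnosis_time, window_end,
                                 thresholds = dka_thresholds()) {
  g <- obs[obs$analyte == "glucose" &
             obs$timestamp >= diagnosis_time &
             obs$timestamp <= window_end, ]
  if (nrow(g) == 0L) {
    rlang::warn("No glucose readings in DKA window; hypoglycaemia taken as absent.",
                class = "dkaudit_no_window_glucose")
    return(FALSE)
  }
  any(g$value < thresholds$hypoglycaemia)
}

#' Complication flags for a whole cohort
#'
#' Flags each episode (once, regardless of how many qualifying readings
#' occur) for hypoglycaemia, hypokalaemia and hyperkalaemia during its DKA
#' window — diagnosis to resolution, or to discharge when unresolved.
#' Hypo- and hyperkalaemia can both be true for one episode (excursions at
#' different times). Episodes with no diagnosis get `NA` flags.
#'
#' @param cohort A `dka_cohort`.
#' @param windows DKA windows from [ascertain_windows()].
#' @param thresholds A [dka_thresholds()] object.
#' @return Tibble with `episode_code`, `hypoglycaemia`, `hypokalaemia`,
#'   `hyperkalaemia`.
#' @export
complication_flags <- function(cohort, windows,
                               thresholds = dka_thresholds()) {
  ep <- cohort$episodes
  obs_by <- split(cohort$observations, cohort$observations$episode_code)
  empty_obs <- cohort$observations[0, ]
  no_glucose <- 0L
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    code <- windows$episode_code[i]
    diag <- windows$diagnosis_time[i]
    if (is.na(diag)) {
      return(tibble::tibble(episode_code = code, hypoglycaemia = NA,
                            hypokalaemia = NA, hyperkalaemia = NA))
    }
    end <- if (windows$resolved[i]) windows$resolution_time[i] else
      ep$discharge[ep$episode_code == code]
    obs <- obs_by[[code]] %||% empty_obs
    hypo <- withCallingHandlers(
      detect_hypoglycaemia(obs, diag, end, thresholds),
      dkaudit_no_window_glucose = function(w) {
        no_glucose <<- no_glucose + 1L
        invokeRestart("muffleWarning")
      })
    k <- obs$value[obs$analyte == "potassium" &
                     obs$timestamp >= diag & obs$timestamp <= end]
    tibble::tibble(
      episode_code = code,
      hypoglycaemia = hypo,
      hypokalaemia = any(k < thresholds$hypokalaemia),
      hyperkalaemia = any(k > thresholds$hyperkalaemia)
    )
  })
  if (no_glucose > 0L) {
    rlang::warn(sprintf("%d episode(s) had no glucose readings in the DKA window.",
                        no_glucose), class = "dkaudit_no_window_glucose_n")
  }
  dplyr::bind_rows(rows)
}

#' Proportion of episodes with a complication
#'
#' Episode-level proportion: episodes flagged at least once divided by all
#' episodes with a non-missing flag.
#'
#' @param flags Complication flags tibble from [complication_flags()].
#' @param which One of `"hypoglycaemia"`, `"hypokalaemia"`, `"hyperkalaemia"`.
#' @return Proportion in \[0, 1\]; `NA` (undefined, not zero) for an empty
#'   input.
#' @export
complication_proportion <- function(flags,
                                    which = c("hypoglycaemia", "hypokalaemia",
                                              "hyperkalaemia")) {
  which <- match.arg(which)
  f <- flags[[which]]
  f <- f[!is.na(f)]
  if (length(f) == 0L) return(NA_real_)
  mean(f)
}

#' Length of stay in days
#'
#' Admission-to-discharge interval in fractional days.
#'
#' @param admission,discharge `POSIXct` timestamps (vectorised).
#' @return Numeric days.
#' @export
length_of_stay_days <- function(admission, discharge) {
  if (any(!is.na(discharge) & !is.na(admission) & discharge < admission)) {
    .abort_domain("`discharge` must not precede `admission`.")
  }
  as.numeric(difftime(discharge, admission, units = "days"))
}

#' Outcome records for a whole cohort
#'
#' @param cohort A `dka_cohort`.
#' @param windows DKA windows from [ascertain_windows()].
#' @return Tibble with `episode_code`, `dka_duration_h` (`NA` when
#'   unresolved), `length_of_stay_d`.
#' @export
outcome_records <- function(cohort, windows) {
  ep <- cohort$episodes
  idx <- match(windows$episode_code, ep$episode_code)
  tibble::tibble(
    episode_code = windows$episode_code,
    dka_duration_h = windows$dka_duration_h,
    length_of_stay_d = length_of_stay_days(ep$admission[idx],
                                           ep$discharge[idx])
  )
}

#' Summarise a cohort's demographics
#'
#' Episode count, median age with interquartile range, sex counts and the
#' women-to-men ratio reported as `"1: r"` with `r = men / women` rounded to
#' two decimals.
#'
#' @param cohort A `dka_cohort`, or its episodes tibble.
#' @param quantile_type Quantile interpolation rule (see [median_iqr()]).
#' @return A list of class `dka_cohort_summary`; `NULL` for an empty cohort.
#' @export
summarize_cohort <- function(cohort, quantile_type = 6) {
  ep <- if (inherits(cohort, "dka_cohort")) cohort$episodes else cohort
  if (nrow(ep) == 0L) return(NULL)
  age <- median_iqr(ep$age_years, quantile_type)
  n_women <- sum(ep$sex == "female")
  n_men <- sum(ep$sex == "male")
  ratio <- if (n_women > 0) round(n_men / n_women, 2) else NA_real_
  structure(
    list(
      n = nrow(ep),
      age_median = age$median, age_q1 = age$q1, age_q3 = age$q3,
      n_women = n_women, n_men = n_men,
      women_to_men_ratio = ratio,
      women_to_men_label = if (is.na(ratio)) NA_character_ else
        sprintf("1: %.2f", ratio)
    ),
    class = "dka_cohort_summary"
  )
}

#' @export
print.dka_cohort_summary <- function(x, ...) {
  cat("<dka_cohort_summary>\n")
  cat(sprintf("  n = %d episodes\n", x$n))
  cat(sprintf("  median age %.1f years (IQR %.1f-%.1f)\n",
              x$age_median, x$age_q1, x$age_q3))
  cat(sprintf("  %d women, %d men (women:men %s)\n",
              x$n_women, x$n_men, x$women_to_men_label))
  invisible(x)
}
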