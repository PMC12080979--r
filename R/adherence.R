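# Per-episode adherence scoring against the four key performance indicators:
# FRIII dosing, fluid replacement, glucose monitoring, ketone monitoring.

#' FRIII adherence
#'
#' Percentage of the recommended fixed-rate insulin infusion (0.1 units/kg/h,
#' configurable through `rate_per_kg`): `(rate / (weight / 10)) * 100` at the
#' default rate. For a 70 kg patient, a 7.0 units/h prescription scores 100%,
#' 3.5 units/h scores 50% and 14.0 units/h scores 200%.
#'
#' @param rate_units_per_h Prescribed infusion rate, units/h (vectorised).
#' @param weight_kg Patient weight, kg.
#' @param rate_per_kg Recommended rate, units/kg/h.
#' @return Adherence percentage(s).
#' @export
#' @examples
#' frii_adherence(7.0, 70)  # 100
#' frii_adherence(3.5, 70)  # 50
frii_adherence <- function(rate_units_per_h, weight_kg, rate_per_kg = 0.1) {
  if (any(!is.na(weight_kg) & weight_kg <= 0)) {
    .abort_domain("`weight_kg` must be strictly positive.")
  }
  if (any(!is.na(rate_units_per_h) & rate_units_per_h < 0)) {
    .abort_domain("`rate_units_per_h` must be non-negative.")
  }
  rate_units_per_h / (weight_kg * rate_per_kg) * 100
}

#' Recommended cumulative fluid volume
#'
#' Guideline fluid volume for a DKA episode of a given duration: the initial
#' bolus plus the scheduled bags. Under `"whole_bag"` accrual (default) a
#' bag's volume is credited once its interval completes, giving a step
#' function worth 2 L at 1 h, 3 L at 3 h, 4 L at 5 h, 5 L at 9 h, 6 L at 13 h
#' and 7 L at 19 h with the default schedule, continuing at 1 L per 6 h until
#' resolution; `"pro_rata"` accrues volume linearly within each bag.
#'
#' @param duration_h DKA duration, hours (vectorised).
#' @param schedule A [fluid_schedule()].
#' @return Recommended volume in litres.
#' @export
#' @examples
#' recommended_fluid_volume(5)  # 4
recommended_fluid_volume <- function(duration_h, schedule = fluid_schedule()) {
  if (any(!is.na(duration_h) & duration_h < 0)) {
    .abort_domain("`duration_h` must be non-negative.")
  }
  ends <- cumsum(schedule$bags$over_hours)
  vols <- schedule$bags$volume_ml
  last_end <- ends[length(ends)]
  vapply(duration_h, function(d) {
    if (is.na(d)) return(NA_real_)
    if (schedule$accrual == "whole_bag") {
      ml <- schedule$bolus_ml + sum(vols[ends <= d])
      if (d > last_end) {
        ml <- ml + floor((d - last_end) / schedule$continuation_hours) *
          schedule$continuation_volume_ml
      }
    } else {
      starts <- c(0, ends[-length(ends)])
      frac <- pmin(pmax((d - starts) / schedule$bags$over_hours, 0), 1)
      ml <- schedule$bolus_ml + sum(vols * frac)
      if (d > last_end) {
        extra <- d - last_end
        n_full <- floor(extra / schedule$continuation_hours)
        rem <- extra - n_full * schedule$continuation_hours
        ml <- ml + n_full * schedule$continuation_volume_ml +
          rem / schedule$continuation_hours * schedule$continuation_volume_ml
      }
    }
    ml / 1000
  }, numeric(1))
}

#' Fluid adherence
#'
#' Administered volume as a percentage of the recommended volume for the
#' episode's DKA duration: 3 L over a 5 h episode scores 75%, 5 L scores
#' 125%.
#'
#' @param administered_l Total fluid volume given during the DKA window,
#'   litres.
#' @param duration_h DKA duration, hours.
#' @param schedule A [fluid_schedule()].
#' @return Adherence percentage(s).
#' @export
#' @examples
#' fluid_adherence(3, 5)  # 75
fluid_adherence <- function(administered_l, duration_h,
                            schedule = fluid_schedule()) {
  if (any(!is.na(administered_l) & administered_l < 0)) {
    .abort_domain("`administered_l` must be non-negative.")
  }
  rec <- recommended_fluid_volume(duration_h, schedule)
  if (any(!is.na(rec) & rec <= 0)) {
    .abort_domain("Recommended volume must be positive.")
  }
  administered_l / rec * 100
}

#' Monitoring adherence
#'
#' Hourly glucose/ketone monitoring adherence: `(readings / duration_h) * 100`.
#' Five readings over a 5 h episode score 100%; 3 and 7 readings score 60%
#' and 140%. A zero-hour duration leaves the score undefined (`NA`, with a
#' warning).
#'
#' @param n_readings Number of readings in the DKA window (vectorised).
#' @param duration_h DKA duration, hours.
#' @return Adherence percentage(s).
#' @export
#' @examples
#' monitoring_adherence(3, 5)  # 60
monitoring_adherence <- function(n_readings, duration_h) {
  if (any(!is.na(n_readings) & n_readings < 0)) {
    .abort_domain("`n_readings` must be non-negative.")
  }
  zero <- !is.na(duration_h) & duration_h == 0
  if (any(zero)) {
    rlang::warn("Zero-hour DKA duration: monitoring adherence undefined.",
                class = "dkaudit_zero_duration")
  }
  out <- n_readings / duration_h * 100
  out[zero] <- NA_real_
  out
}

#' Adherence band membership
#'
#' `TRUE` when the score lies within the inclusive adherence band
#' (80%-120% by default), the +/-20% window around the guideline
#' recommendation; banding is computed at full precision.
#'
#' @param pct Adherence percentage(s).
#' @param thresholds A [dka_thresholds()] object.
#' @return Logical (`NA` where `pct` is `NA`).
#' @export
within_band <- function(pct, thresholds = dka_thresholds()) {
  pct >= thresholds$band_low & pct <= thresholds$band_high
}

# Distinct reading times of one analyte within the closed DKA window;
# duplicate charting at the same minute counts once.
.n_readings_in_window <- function(obs, analyte, from, to) {
  t <- obs$timestamp[obs$analyte == analyte]
  length(unique(t[t >= from & t <= to]))
}

#' Score adherence for a whole cohort
#'
#' Assembles the four per-episode adherence indicators and their band flags.
#' The FRIII score uses the first FRIII prescription by start time (the
#' initial rate; ties keep file order) and is computed even for unresolved
#' episodes. Fluid and monitoring scores need a resolved DKA window: the
#' fluid score uses the sum of fluid volumes with a start time inside the
#' closed window, the monitoring scores count distinct glucose / ketone
#' reading times inside it. Episodes with no FRIII prescription or no
#' recorded weight have an absent FRIII score (the latter with a warning).
#'
#' @param cohort A `dka_cohort`.
#' @param windows DKA windows from [ascertain_windows()].
#' @param thresholds A [dka_thresholds()] object.
#' @param schedule A [fluid_schedule()].
#' @return Tibble with `episode_code`, `frii_pct`, `fluid_pct`, `glucose_pct`,
#'   `ketone_pct` and matching `*_in_band` flags.
#' @export
score_adherence <- function(cohort, windows, thresholds = dka_thresholds(),
                            schedule = fluid_schedule()) {
  ep <- cohort$episodes
  rx_by <- split(cohort$prescriptions, cohort$prescriptions$episode_code)
  obs_by <- split(cohort$observations, cohort$observations$episode_code)
  empty_rx <- cohort$prescriptions[0, ]
  empty_obs <- cohort$observations[0, ]
  missing_weight <- 0L

  rows <- lapply(seq_len(nrow(windows)), function(i) {
    code <- windows$episode_code[i]
    e <- ep[ep$episode_code == code, ]
    rx <- rx_by[[code]] %||% empty_rx
    obs <- obs_by[[code]] %||% empty_obs

    frii_pct <- NA_real_
    frii_rx <- rx[rx$kind == "frii", ]
    if (nrow(frii_rx) > 0) {
      first <- frii_rx[order(frii_rx$start)[1], ]
      if (is.na(e$weight_kg)) {
        missing_weight <<- missing_weight + 1L
      } else {
        frii_pct <- frii_adherence(first$rate_units_per_h, e$weight_kg,
                                   thresholds$frii_rate_per_kg)
      }
    }

    fluid_pct <- glucose_pct <- ketone_pct <- NA_real_
    if (isTRUE(windows$resolved[i])) {
      from <- windows$diagnosis_time[i]
      to <- windows$resolution_time[i]
      dur <- windows$dka_duration_h[i]
      fluid_rx <- rx[rx$kind == "fluid" & rx$start >= from & rx$start <= to, ]
      administered_l <- sum(fluid_rx$volume_ml) / 1000
      fluid_pct <- fluid_adherence(administered_l, dur, schedule)
      if (dur > 0) {
        glucose_pct <- monitoring_adherence(
          .n_readings_in_window(obs, "glucose", from, to), dur)
        ketone_pct <- monitoring_adherence(
          .n_readings_in_window(obs, "ketones", from, to), dur)
      }
    }

    tibble::tibble(
      episode_code = code,
      frii_pct = frii_pct, fluid_pct = fluid_pct,
      glucose_pct = glucose_pct, ketone_pct = ketone_pct
    )
  })
  out <- dplyr::bind_rows(rows)
  if (missing_weight > 0L) {
    rlang::warn(sprintf(
      "%d episode(s) have an FRIII prescription but no recorded weight; FRIII score absent.",
      missing_weight), class = "dkaudit_missing_weight")
  }
  out$frii_in_band <- within_band(out$frii_pct, thresholds)
  out$fluid_in_band <- within_band(out$fluid_pct, thresholds)
  out$glucose_in_band <- within_band(out$glucose_pct, thresholds)
  out$ketone_in_band <- within_band(out$ketone_pct, thresholds)
  out
}
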