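# Clinical thresholds and the guideline fluid-replacement schedule.

#' Clinical thresholds for DKA ascertainment, complications and banding
#'
#' Bundles every cut-off the pipeline uses, defaulted to the JBDS-IP adult DKA
#' guideline values. Diagnosis requires (glucose > `dka_glucose` mmol/L OR a
#' known history of diabetes) AND ketones > `dka_ketones` mmol/L AND
#' (pH < `dka_ph` OR bicarbonate < `dka_bicarbonate` mmol/L). Resolution
#' requires (pH > `res_ph` OR bicarbonate > `res_bicarbonate` mmol/L) AND
#' blood ketones < `res_ketones` mmol/L sustained over two consecutive
#' readings.
#'
#' @param dka_glucose Diagnostic glucose threshold, mmol/L.
#' @param dka_ketones Diagnostic blood-ketone threshold, mmol/L.
#' @param dka_ph Diagnostic pH threshold.
#' @param dka_bicarbonate Diagnostic bicarbonate threshold, mmol/L.
#' @param res_ph Resolution pH threshold.
#' @param res_bicarbonate Resolution bicarbonate threshold, mmol/L.
#' @param res_ketones Resolution blood-ketone threshold, mmol/L.
#' @param hypoglycaemia Complication glucose threshold (strictly below), mmol/L.
#' @param hypokalaemia Potassium threshold (strictly below), mmol/L.
#' @param hyperkalaemia Potassium threshold (strictly above), mmol/L.
#' @param frii_rate_per_kg Recommended fixed-rate insulin infusion, units/kg/h.
#' @param band_low,band_high Inclusive adherence band bounds, percent.
#' @param lookback_h Staleness window: a reading older than this many hours
#'   before the evaluation time is ignored when taking "the most recent
#'   reading" of an analyte.
#' @param res_gap_min,res_gap_tol_min The "two consecutive hours" resolution
#'   rule is read as two qualifying readings `res_gap_min` +/- `res_gap_tol_min`
#'   minutes apart.
#' @param res_mark Whether the resolution is stamped at the `"second"`
#'   (default: the moment the sustained criterion is confirmed) or `"first"`
#'   reading of the qualifying pair.
#' @return A list of class `dka_thresholds`.
#' @export
#' @examples
#' th <- dka_thresholds()
#' th$band_low
dka_thresholds <- function(dka_glucose = 11,
                           dka_ketones = 3,
                           dka_ph = 7.30,
                           dka_bicarbonate = 15,
                           res_ph = 7.30,
                           res_bicarbonate = 18,
                           res_ketones = 0.6,
                           hypoglycaemia = 4,
                           hypokalaemia = 3.5,
                           hyperkalaemia = 5.5,
                           frii_rate_per_kg = 0.1,
                           band_low = 80,
                           band_high = 120,
                           lookback_h = 6,
                           res_gap_min = 60,
                           res_gap_tol_min = 15,
                           res_mark = c("second", "first")) {
  res_mark <- match.arg(res_mark)
  th <- list(
    dka_glucose = dka_glucose, dka_ketones = dka_ketones, dka_ph = dka_ph,
    dka_bicarbonate = dka_bicarbonate, res_ph = res_ph,
    res_bicarbonate = res_bicarbonate, res_ketones = res_ketones,
    hypoglycaemia = hypoglycaemia, hypokalaemia = hypokalaemia,
    hyperkalaemia = hyperkalaemia, frii_rate_per_kg = frii_rate_per_kg,
    band_low = band_low, band_high = band_high, lookback_h = lookback_h,
    res_gap_min = res_gap_min, res_gap_tol_min = res_gap_tol_min,
    res_mark = res_mark
  )
  num <- th[!(names(th) %in% "res_mark")]
  if (!all(vapply(num, function(v) is.numeric(v) && length(v) == 1L &&
                    is.finite(v) && v > 0, logical(1)))) {
    .abort_config("All thresholds must be strictly positive finite scalars.")
  }
  if (th$band_low >= th$band_high) {
    .abort_config("`band_low` must be below `band_high`.")
  }
  if (th$res_gap_tol_min >= th$res_gap_min) {
    .abort_config("`res_gap_tol_min` must be smaller than `res_gap_min`.")
  }
  structure(th, class = "dka_thresholds")
}

#' @export
print.dka_thresholds <- function(x, ...) {
  cat("<dka_thresholds>\n")
  cat(sprintf("  diagnosis : glucose > %g | history; ketones > %g; pH < %g | bicarbonate < %g\n",
              x$dka_glucose, x$dka_ketones, x$dka_ph, x$dka_bicarbonate))
  cat(sprintf("  resolution: pH > %g | bicarbonate > %g; ketones < %g (two readings %g±%g min, mark %s)\n",
              x$res_ph, x$res_bicarbonate, x$res_ketones, x$res_gap_min,
              x$res_gap_tol_min, x$res_mark))
  cat(sprintf("  band      : [%g%%, %g%%]; FRIII %g u/kg/h; lookback %g h\n",
              x$band_low, x$band_high, x$frii_rate_per_kg, x$lookback_h))
  invisible(x)
}

#' Guideline fluid-replacement schedule
#'
#' The adult DKA fluid recommendation: an initial bolus (two 500 mL boluses,
#' counted as 1000 mL in total), then 1 L bags over 1 h, 2 h, 2 h, 4 h, 4 h
#' and 6 h, followed by further 1 L bags over 6 h each until resolution. With
#' the default `"whole_bag"` accrual a bag's volume is credited when its
#' interval completes, which reproduces the guideline anchor of 4 L
#' recommended for a 5-hour episode; `"pro_rata"` credits volume linearly
#' within each bag instead.
#'
#' @param bolus_ml Initial bolus volume, mL.
#' @param bags Two-column matrix-like data frame (`volume_ml`, `over_hours`)
#'   of scheduled bags in order.
#' @param continuation_volume_ml,continuation_hours The bag repeated until
#'   resolution once the listed bags are exhausted.
#' @param accrual `"whole_bag"` or `"pro_rata"` volume accrual.
#' @return A list of class `fluid_schedule`.
#' @export
#' @examples
#' recommended_fluid_volume(5, fluid_schedule()) # 4 L
fluid_schedule <- function(bolus_ml = 1000,
                           bags = data.frame(
                             volume_ml = rep(1000, 6),
                             over_hours = c(1, 2, 2, 4, 4, 6)
                           ),
                           continuation_volume_ml = 1000,
                           continuation_hours = 6,
                           accrual = c("whole_bag", "pro_rata")) {
  accrual <- match.arg(accrual)
  bags <- as.data.frame(bags)
  if (!all(c("volume_ml", "over_hours") %in% names(bags))) {
    .abort_config("`bags` must have columns `volume_ml` and `over_hours`.")
  }
  ok <- all(bags$volume_ml > 0) && all(bags$over_hours > 0) &&
    bolus_ml > 0 && continuation_volume_ml > 0 && continuation_hours > 0
  if (!isTRUE(ok)) {
    .abort_config("All schedule volumes and durations must be strictly positive.")
  }
  structure(
    list(bolus_ml = bolus_ml, bags = bags,
         continuation_volume_ml = continuation_volume_ml,
         continuation_hours = continuation_hours, accrual = accrual),
    class = "fluid_schedule"
  )
}

#' @export
print.fluid_schedule <- function(x, ...) {
  cat("<fluid_schedule>\n")
  cat(sprintf("  bolus %g mL; bags %s; then %g mL / %g h until resolution (%s accrual)\n",
              x$bolus_ml,
              paste(sprintf("%g mL/%g h", x$bags$volume_ml, x$bags$over_hours),
                    collapse = ", "),
              x$continuation_volume_ml, x$continuation_hours, x$accrual))
  invisible(x)
}

#' ICD-10 discharge codes used to screen for DKA
#'
#' Diabetes-with-coma and diabetes-with-ketoacidosis codes (E10-E14, fourth
#' digit 0 or 1).
#'
#' @return Character vector of ICD-10 codes.
#' @export
dka_icd10_codes <- function() {
  c("E10.0", "E11.0", "E12.0", "E13.0", "E14.0",
    "E10.1", "E11.1", "E12.1", "E13.1", "E14.1")
}

#' Read pipeline configuration from YAML
#'
#' Reads an optional YAML file with `thresholds:` and `fluid_schedule:` blocks
#' whose entries override the corresponding arguments of [dka_thresholds()]
#' and [fluid_schedule()]. Missing blocks fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `thresholds` and `schedule`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    .abort_config(sprintf("Config file not found: %s", path))
  }
  raw <- yaml::read_yaml(path)
  th_args <- raw$thresholds %||% list()
  sc_args <- raw$fluid_schedule %||% list()
  if (!is.null(sc_args$bags)) {
    sc_args$bags <- do.call(rbind, lapply(sc_args$bags, function(b) {
      data.frame(volume_ml = b[[1]], over_hours = b[[2]])
    }))
  }
  list(
    thresholds = do.call(dka_thresholds, th_args),
    schedule = do.call(fluid_schedule, sc_args)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
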