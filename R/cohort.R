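# The cohort container and flat-file readers/writers.
#
# A cohort is four linked tibbles mirroring the flat CSV registry extract:
# episodes (one row per DKA admission), observations (timestamped analyte
# readings), prescriptions (insulin infusion rates and fluid volumes) and
# discharge codes (ICD-10). Validation is total: every malformed row is
# reported with its file, row number and field; nothing is silently coerced.

.ANALYTES <- c("glucose", "ketones", "ph", "bicarbonate", "potassium", "sbp")
.SEXES <- c("female", "male")
.DIABETES_TYPES <- c("t1dm", "t2dm", "unknown")

.EPISODE_COLS <- c("episode_code", "hospital_code", "age_years", "sex",
                   "diabetes_type", "has_diabetes_history", "weight_kg",
                   "admission", "discharge")
.OBS_COLS <- c("episode_code", "timestamp", "analyte", "value")
.RX_COLS <- c("episode_code", "kind", "rate_units_per_h", "volume_ml", "start")
.CODE_COLS <- c("episode_code", "icd10")

#' Construct a DKA cohort
#'
#' Assembles the four linked tables into a validated `dka_cohort` object.
#' Observations are sorted non-decreasing by timestamp within each episode
#' (stable, so ties keep file order).
#'
#' @param episodes Tibble with columns `episode_code`, `hospital_code`,
#'   `age_years`, `sex`, `diabetes_type`, `has_diabetes_history`, `weight_kg`,
#'   `admission`, `discharge`, and optionally `urine_ketones` (urine ketones
#'   at least ++ on admission) and `confirmed` (manual adjudication override).
#' @param observations Tibble with `episode_code`, `timestamp`, `analyte`,
#'   `value`.
#' @param prescriptions Tibble with `episode_code`, `kind` (`"frii"` or
#'   `"fluid"`), `rate_units_per_h`, `volume_ml`, `start`. Exactly one of
#'   rate/volume is populated per row, matching the kind.
#' @param discharge_codes Tibble with `episode_code`, `icd10`.
#' @return A list of class `dka_cohort`.
#' @export
dka_cohort <- function(episodes, observations, prescriptions, discharge_codes) {
  episodes <- tibble::as_tibble(episodes)
  if (!"urine_ketones" %in% names(episodes)) {
    episodes$urine_ketones <- rep(FALSE, nrow(episodes))
  }
  if (!"confirmed" %in% names(episodes)) {
    episodes$confirmed <- rep(NA, nrow(episodes))
  }
  observations <- dplyr::arrange(tibble::as_tibble(observations),
                                 .data$episode_code, .data$timestamp)
  x <- structure(
    list(
      episodes = episodes,
      observations = observations,
      prescriptions = tibble::as_tibble(prescriptions),
      discharge_codes = tibble::as_tibble(discharge_codes)
    ),
    class = "dka_cohort"
  )
  validate_dka_cohort(x)
  x
}

#' Validate a DKA cohort
#'
#' Checks the structural invariants of a [dka_cohort()]: required columns,
#' enumerations, value ranges (pH in \[6.5, 8\], other analytes non-negative),
#' age at least 16 years, discharge not before admission, one-of rate/volume
#' per prescription, ICD-10 code syntax, observations sorted by time, and no
#' observation/prescription/code referencing an unknown episode.
#'
#' @param x A `dka_cohort`.
#' @return `x`, invisibly; aborts with a classed condition on violation.
#' @export
validate_dka_cohort <- function(x) {
  ep <- x$episodes
  .check_cols(ep, .EPISODE_COLS, "episodes")
  .check_cols(x$observations, .OBS_COLS, "observations")
  .check_cols(x$prescriptions, .RX_COLS, "prescriptions")
  .check_cols(x$discharge_codes, .CODE_COLS, "discharge_codes")

  if (nrow(ep) > 0) {
    .row_check(!is.na(ep$episode_code) & nzchar(ep$episode_code),
               "episodes", "episode_code", "must be non-empty")
    if (anyDuplicated(ep$episode_code)) {
      .abort_row(sprintf("episodes: duplicated episode_code at row %d",
                         anyDuplicated(ep$episode_code)))
    }
    .row_check(ep$sex %in% .SEXES, "episodes", "sex",
               sprintf("must be one of: %s", paste(.SEXES, collapse = ", ")))
    .row_check(ep$diabetes_type %in% .DIABETES_TYPES, "episodes",
               "diabetes_type",
               sprintf("must be one of: %s",
                       paste(.DIABETES_TYPES, collapse = ", ")))
    .row_check(!is.na(ep$age_years) & ep$age_years >= 16, "episodes",
               "age_years", "must be >= 16 (adult inclusion criterion)")
    .row_check(!is.na(ep$weight_kg) & ep$weight_kg > 0, "episodes",
               "weight_kg", "must be > 0", allow_na = TRUE,
               na_ok = is.na(ep$weight_kg))
    .row_check(!is.na(ep$admission), "episodes", "admission",
               "must be a valid timestamp")
    .row_check(!is.na(ep$discharge), "episodes", "discharge",
               "must be a valid timestamp")
    .row_check(ep$discharge >= ep$admission, "episodes", "discharge",
               "must not precede admission")
  }

  ob <- x$observations
  if (nrow(ob) > 0) {
    .row_check(ob$analyte %in% .ANALYTES, "observations", "analyte",
               sprintf("must be one of: %s", paste(.ANALYTES, collapse = ", ")))
    .row_check(!is.na(ob$timestamp), "observations", "timestamp",
               "must be a valid timestamp")
    .row_check(is.finite(ob$value), "observations", "value",
               "must be finite")
    is_ph <- ob$analyte == "ph"
    .row_check(!is_ph | (ob$value >= 6.5 & ob$value <= 8.0),
               "observations", "value", "pH must lie in [6.5, 8.0]")
    .row_check(is_ph | ob$value >= 0, "observations", "value",
               "must be non-negative")
    orphan <- !(ob$episode_code %in% ep$episode_code)
    if (any(orphan)) {
      .abort_orphan(sprintf(
        "observations: row %d references unknown episode_code '%s'",
        which(orphan)[1], ob$episode_code[which(orphan)[1]]))
    }
    unsorted <- unlist(lapply(split(as.numeric(ob$timestamp), ob$episode_code),
                              is.unsorted), use.names = FALSE)
    if (any(unsorted)) {
      .abort_row("observations: not sorted by timestamp within episode")
    }
  }

  rx <- x$prescriptions
  if (nrow(rx) > 0) {
    .row_check(rx$kind %in% c("frii", "fluid"), "prescriptions", "kind",
               "must be 'frii' or 'fluid'")
    .row_check(!is.na(rx$start), "prescriptions", "start",
               "must be a valid timestamp")
    frii <- rx$kind == "frii"
    .row_check(!frii | (!is.na(rx$rate_units_per_h) & is.na(rx$volume_ml)),
               "prescriptions", "rate_units_per_h",
               "frii rows must carry a rate and no volume")
    .row_check(frii | (!is.na(rx$volume_ml) & is.na(rx$rate_units_per_h)),
               "prescriptions", "volume_ml",
               "fluid rows must carry a volume and no rate")
    .row_check(is.na(rx$rate_units_per_h) | rx$rate_units_per_h >= 0,
               "prescriptions", "rate_units_per_h", "must be >= 0")
    .row_check(is.na(rx$volume_ml) | rx$volume_ml >= 0,
               "prescriptions", "volume_ml", "must be >= 0")
    orphan <- !(rx$episode_code %in% ep$episode_code)
    if (any(orphan)) {
      .abort_orphan(sprintf(
        "prescriptions: row %d references unknown episode_code '%s'",
        which(orphan)[1], rx$episode_code[which(orphan)[1]]))
    }
  }

  dc <- x$discharge_codes
  if (nrow(dc) > 0) {
    .row_check(grepl("^[A-Z][0-9]{2}(\\.[0-9])?$", dc$icd10),
               "discharge_codes", "icd10",
               "must match letter + two digits + optional '.digit'")
    orphan <- !(dc$episode_code %in% ep$episode_code)
    if (any(orphan)) {
      .abort_orphan(sprintf(
        "discharge_codes: row %d references unknown episode_code '%s'",
        which(orphan)[1], dc$episode_code[which(orphan)[1]]))
    }
  }
  invisible(x)
}

.check_cols <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    .abort_schema(sprintf("%s: missing required column(s): %s",
                          file, paste(missing, collapse = ", ")))
  }
}

.row_check <- function(ok, file, field, msg, allow_na = FALSE, na_ok = NULL) {
  if (allow_na) ok <- ok | na_ok
  ok[is.na(ok)] <- FALSE
  if (!all(ok)) {
    .abort_row(sprintf("%s: row %d, field '%s' %s",
                       file, which(!ok)[1], field, msg))
  }
}

#' @export
print.dka_cohort <- function(x, ...) {
  cat("<dka_cohort>\n")
  cat(sprintf("  %d episodes across %d hospital(s)\n",
              nrow(x$episodes), length(unique(x$episodes$hospital_code))))
  cat(sprintf("  %d observations, %d prescriptions, %d discharge codes\n",
              nrow(x$observations), nrow(x$prescriptions),
              nrow(x$discharge_codes)))
  if (nrow(x$episodes) > 0) {
    cat(sprintf("  admissions %s to %s\n",
                .format_minute(min(x$episodes$admission)),
                .format_minute(max(x$episodes$admission))))
  }
  invisible(x)
}

# -- reading ------------------------------------------------------------------

.read_raw <- function(path, file) {
  if (!file.exists(path)) {
    .abort_schema(sprintf("%s: file not found: %s", file, path))
  }
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

.parse_num_col <- function(x, file, field, allow_na = FALSE) {
  out <- suppressWarnings(as.numeric(x))
  blank <- is.na(x) | !nzchar(trimws(x))
  bad <- !blank & is.na(out)
  if (any(bad)) {
    .abort_row(sprintf("%s: row %d, field '%s' is not numeric: '%s'",
                       file, which(bad)[1], field, x[which(bad)[1]]))
  }
  if (!allow_na && any(blank)) {
    .abort_row(sprintf("%s: row %d, field '%s' is missing",
                       file, which(blank)[1], field))
  }
  out
}

.parse_time_col <- function(x, file, field) {
  out <- .parse_minute(x)
  bad <- is.na(out)
  if (any(bad)) {
    .abort_row(sprintf(
      "%s: row %d, field '%s' is not a 'YYYY-MM-DDTHH:MM' timestamp: '%s'",
      file, which(bad)[1], field, x[which(bad)[1]]))
  }
  out
}

.parse_bool_col <- function(x, file, field, default = NA) {
  blank <- is.na(x) | !nzchar(trimws(x))
  low <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[low %in% c("true", "1", "yes")] <- TRUE
  out[low %in% c("false", "0", "no")] <- FALSE
  bad <- !blank & is.na(out)
  if (any(bad)) {
    .abort_row(sprintf("%s: row %d, field '%s' is not a boolean: '%s'",
                       file, which(bad)[1], field, x[which(bad)[1]]))
  }
  out[blank] <- default
  out
}

#' Read a cohort from flat CSV files
#'
#' Materialises the four registry tables into a validated [dka_cohort()].
#' Observations arriving out of time order are re-sorted (stably) within each
#' episode. Malformed input aborts with a classed condition naming the file,
#' row and field; records referencing an unknown episode raise an
#' orphan-record error.
#'
#' @param episodes_path,observations_path,prescriptions_path,codes_path Paths
#'   to `episodes.csv`, `observations.csv`, `prescriptions.csv` and
#'   `discharge_codes.csv` (schemas in the package vignette).
#' @return A `dka_cohort`.
#' @export
read_cohort <- function(episodes_path, observations_path, prescriptions_path,
                        codes_path) {
  raw_ep <- .read_raw(episodes_path, "episodes")
  .check_cols(raw_ep, .EPISODE_COLS, "episodes")
  episodes <- tibble::tibble(
    episode_code = raw_ep$episode_code,
    hospital_code = raw_ep$hospital_code,
    age_years = as.integer(.parse_num_col(raw_ep$age_years, "episodes", "age_years")),
    sex = raw_ep$sex,
    diabetes_type = raw_ep$diabetes_type,
    has_diabetes_history = .parse_bool_col(raw_ep$has_diabetes_history,
                                           "episodes", "has_diabetes_history",
                                           default = FALSE),
    weight_kg = .parse_num_col(raw_ep$weight_kg, "episodes", "weight_kg",
                               allow_na = TRUE),
    admission = .parse_time_col(raw_ep$admission, "episodes", "admission"),
    discharge = .parse_time_col(raw_ep$discharge, "episodes", "discharge"),
    urine_ketones = if ("urine_ketones" %in% names(raw_ep)) {
      .parse_bool_col(raw_ep$urine_ketones, "episodes", "urine_ketones",
                      default = FALSE)
    } else rep(FALSE, nrow(raw_ep)),
    confirmed = if ("confirmed" %in% names(raw_ep)) {
      .parse_bool_col(raw_ep$confirmed, "episodes", "confirmed", default = NA)
    } else rep(NA, nrow(raw_ep))
  )

  raw_ob <- .read_raw(observations_path, "observations")
  .check_cols(raw_ob, .OBS_COLS, "observations")
  observations <- tibble::tibble(
    episode_code = raw_ob$episode_code,
    timestamp = .parse_time_col(raw_ob$timestamp, "observations", "timestamp"),
    analyte = raw_ob$analyte,
    value = .parse_num_col(raw_ob$value, "observations", "value")
  )

  raw_rx <- .read_raw(prescriptions_path, "prescriptions")
  .check_cols(raw_rx, .RX_COLS, "prescriptions")
  prescriptions <- tibble::tibble(
    episode_code = raw_rx$episode_code,
    kind = raw_rx$kind,
    rate_units_per_h = .parse_num_col(raw_rx$rate_units_per_h, "prescriptions",
                                      "rate_units_per_h", allow_na = TRUE),
    volume_ml = .parse_num_col(raw_rx$volume_ml, "prescriptions", "volume_ml",
                               allow_na = TRUE),
    start = .parse_time_col(raw_rx$start, "prescriptions", "start")
  )

  raw_dc <- .read_raw(codes_path, "discharge_codes")
  .check_cols(raw_dc, .CODE_COLS, "discharge_codes")
  discharge_codes <- tibble::tibble(
    episode_code = raw_dc$episode_code,
    icd10 = raw_dc$icd10
  )

  dka_cohort(episodes, observations, prescriptions, discharge_codes)
}

# -- writing ------------------------------------------------------------------

.fmt_bool <- function(x) ifelse(is.na(x), "", ifelse(x, "true", "false"))

#' Write a cohort to flat CSV files
#'
#' Inverse of [read_cohort()]: `read_cohort()` applied to the written files
#' reproduces the cohort field for field. Timestamps are written at minute
#' resolution (`YYYY-MM-DDTHH:MM`); booleans as `true`/`false`.
#'
#' @param cohort A `dka_cohort`.
#' @param directory Output directory (created if absent).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  validate_dka_cohort(cohort)
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) rlang::abort(sprintf("Cannot create directory: %s", directory),
                          class = "dkaudit_io_error")
  }
  ep <- cohort$episodes
  ep_out <- tibble::tibble(
    episode_code = ep$episode_code,
    hospital_code = ep$hospital_code,
    age_years = ep$age_years,
    sex = ep$sex,
    diabetes_type = ep$diabetes_type,
    has_diabetes_history = .fmt_bool(ep$has_diabetes_history),
    weight_kg = ep$weight_kg,
    admission = .format_minute(ep$admission),
    discharge = .format_minute(ep$discharge),
    urine_ketones = .fmt_bool(ep$urine_ketones),
    confirmed = .fmt_bool(ep$confirmed)
  )
  ob <- cohort$observations
  ob_out <- tibble::tibble(
    episode_code = ob$episode_code,
    timestamp = .format_minute(ob$timestamp),
    analyte = ob$analyte,
    value = ob$value
  )
  rx <- cohort$prescriptions
  rx_out <- tibble::tibble(
    episode_code = rx$episode_code,
    kind = rx$kind,
    rate_units_per_h = rx$rate_units_per_h,
    volume_ml = rx$volume_ml,
    start = .format_minute(rx$start)
  )
  paths <- c(
    episodes = file.path(directory, "episodes.csv"),
    observations = file.path(directory, "observations.csv"),
    prescriptions = file.path(directory, "prescriptions.csv"),
    discharge_codes = file.path(directory, "discharge_codes.csv")
  )
  readr::write_csv(ep_out, paths[["episodes"]], progress = FALSE)
  readr::write_csv(ob_out, paths[["observations"]], progress = FALSE)
  readr::write_csv(rx_out, paths[["prescriptions"]], progress = FALSE)
  readr::write_csv(cohort$discharge_codes, paths[["discharge_codes"]],
                   progress = FALSE)
  invisible(paths)
}
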