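# Fixture builders and independent brute-force oracles used across tests.

tmin <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M", tz = "UTC")

obs_tbl <- function(times, analyte, value, code = "ep1") {
  tibble::tibble(
    episode_code = code,
    timestamp = if (inherits(times, "POSIXct")) times else tmin(times),
    analyte = analyte,
    value = value
  )
}

episode_row <- function(code = "ep1", hospital = "A", age = 45,
                        sex = "female", type = "t1dm", history = TRUE,
                        weight = 70, admission = "2022-01-01T08:00",
                        discharge = "2022-01-04T08:00") {
  tibble::tibble(
    episode_code = code, hospital_code = hospital, age_years = as.integer(age),
    sex = sex, diabetes_type = type, has_diabetes_history = history,
    weight_kg = weight, admission = tmin(admission), discharge = tmin(discharge)
  )
}

# A hand-built, fully adherent single episode: diagnosis at 08:00, resolution
# at 13:00 (5 h), 5 glucose and 5 ketone readings in the window, FRIII at
# 0.1 u/kg/h, fluids exactly at the recommended 4 L.
adherent_cohort <- function(code = "ep1") {
  t0 <- tmin("2022-01-01T08:00")
  hours <- function(h) t0 + h * 3600
  obs <- dplyr::bind_rows(
    obs_tbl(hours(c(0, 1, 2, 4, 5)), "glucose", c(25, 20, 15, 10, 9), code),
    obs_tbl(hours(c(0, 1, 3, 4, 5)), "ketones", c(5.5, 4.0, 1.0, 0.3, 0.2), code),
    obs_tbl(hours(0:5), "ph", c(7.05, 7.1, 7.15, 7.2, 7.35, 7.4), code),
    obs_tbl(hours(0:5), "bicarbonate", c(10, 11, 12, 14, 20, 22), code),
    obs_tbl(hours(c(0, 3)), "potassium", c(4.5, 4.2), code)
  )
  rx <- tibble::tibble(
    episode_code = code,
    kind = c("frii", "fluid", "fluid", "fluid", "fluid"),
    rate_units_per_h = c(7, NA, NA, NA, NA),
    volume_ml = c(NA, 1000, 1000, 1000, 1000),
    start = c(t0, t0, hours(1), hours(2), hours(4))
  )
  dka_cohort(
    episode_row(code),
    obs,
    rx,
    tibble::tibble(episode_code = code, icd10 = "E10.1")
  )
}

# ---- independent brute-force oracles ---------------------------------------

oracle_latest <- function(obs, analyte, at, lookback_h) {
  sel <- obs$analyte == analyte & obs$timestamp <= at &
    as.numeric(at) - as.numeric(obs$timestamp) <= lookback_h * 3600
  if (!any(sel)) return(NA_real_)
  tt <- obs$timestamp[sel]
  vv <- obs$value[sel]
  vv[which(as.numeric(tt) == max(as.numeric(tt)))[1]]
}

oracle_criteria <- function(obs, at, history, th) {
  g <- oracle_latest(obs, "glucose", at, th$lookback_h)
  k <- oracle_latest(obs, "ketones", at, th$lookback_h)
  ph <- oracle_latest(obs, "ph", at, th$lookback_h)
  bic <- oracle_latest(obs, "bicarbonate", at, th$lookback_h)
  garm <- history || (!is.na(g) && g > th$dka_glucose)
  karm <- if (is.na(k)) NA else k > th$dka_ketones
  aarm <- if (is.na(ph) && is.na(bic)) NA else
    isTRUE(ph < th$dka_ph) || isTRUE(bic < th$dka_bicarbonate)
  garm & karm & aarm
}

oracle_diagnosis <- function(obs, history, th) {
  for (at in sort(unique(obs$timestamp))) {
    at <- as.POSIXct(at, origin = "1970-01-01", tz = "UTC")
    if (isTRUE(oracle_criteria(obs, at, history, th))) return(at)
  }
  as.POSIXct(NA_real_, origin = "1970-01-01", tz = "UTC")
}

oracle_res_holds <- function(obs, at, th) {
  k <- oracle_latest(obs, "ketones", at, th$lookback_h)
  ph <- oracle_latest(obs, "ph", at, th$lookback_h)
  bic <- oracle_latest(obs, "bicarbonate", at, th$lookback_h)
  (isTRUE(ph > th$res_ph) || isTRUE(bic > th$res_bicarbonate)) &&
    isTRUE(k < th$res_ketones)
}

# exhaustive all-pairs scan; earliest qualifying pair by its second member
oracle_resolution <- function(obs, diag, th, until = NULL) {
  ts <- sort(unique(obs$timestamp))
  ts <- ts[ts > diag]
  if (!is.null(until)) ts <- ts[ts <= until]
  qual <- ts[vapply(ts, function(t) oracle_res_holds(obs, t, th), logical(1))]
  best <- Inf
  lo <- (th$res_gap_min - th$res_gap_tol_min) * 60
  hi <- (th$res_gap_min + th$res_gap_tol_min) * 60
  q <- as.numeric(qual)
  if (length(q) >= 2) {
    for (i in seq_along(q)) {
      for (jj in seq_along(q)) {
        if (q[jj] > q[i] && q[jj] - q[i] >= lo && q[jj] - q[i] <= hi) {
          best <- min(best, q[jj])
        }
      }
    }
  }
  if (is.infinite(best)) as.POSIXct(NA_real_, origin = "1970-01-01", tz = "UTC")
  else as.POSIXct(best, origin = "1970-01-01", tz = "UTC")
}

# random episode with readings clustered around the decision thresholds, so
# diagnosis/resolution scans hit genuine boundary cases
random_episode_obs <- function(max_readings = 40, code = "ep1") {
  n <- sample(3:max_readings, 1)
  t0 <- tmin("2022-03-01T06:00")
  times <- t0 + sort(sample(0:(48 * 60), n, replace = TRUE)) * 60
  analyte <- sample(c("glucose", "ketones", "ph", "bicarbonate"), n,
                    replace = TRUE, prob = c(0.3, 0.3, 0.2, 0.2))
  value <- vapply(analyte, function(a) {
    switch(a,
           glucose = round(stats::runif(1, 3, 30), 1),
           ketones = round(stats::runif(1, 0, 6), 1),
           ph = round(stats::runif(1, 6.9, 7.6), 2),
           bicarbonate = round(stats::runif(1, 8, 30), 1))
  }, numeric(1))
  obs_tbl(times, analyte, value, code)
}

random_thresholds <- function() {
  dka_thresholds(
    dka_glucose = sample(c(10, 11, 12), 1),
    dka_ketones = stats::runif(1, 2.5, 3.5),
    dka_ph = stats::runif(1, 7.25, 7.35),
    dka_bicarbonate = stats::runif(1, 13, 17),
    res_ph = stats::runif(1, 7.25, 7.35),
    res_bicarbonate = stats::runif(1, 16, 20),
    res_ketones = stats::runif(1, 0.4, 1.0),
    lookback_h = sample(c(4, 6, 8), 1),
    res_gap_tol_min = sample(c(10, 15, 20), 1)
  )
}

small_sim <- function(seed = 11, per_quarter = 8, hospitals = c("A", "B"),
                      onboard = c("2022-Q1", "2022-Q2"), ...) {
  generate_cohort(sim_config(
    seed = seed,
    hospitals = data.frame(code = hospitals, onboard_quarter = onboard,
                           episodes_per_quarter = per_quarter,
                           poisson = FALSE),
    end_quarter = "2022-Q4", ...
  ))
}

# Half-width of the recovery interval for one of `m` simultaneous binomial
# comparisons, holding the family-wise error of the whole recovery check at 5%.
recovery_halfwidth <- function(p, n, m = 7) {
  stats::qnorm(1 - 0.025 / m) * sqrt(p * (1 - p) / n)
}
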