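# Synthetic multi-hospital DKA cohort generator with a ground-truth table.
#
# Each generated episode carries a diagnosis-time lab panel satisfying the
# diagnostic criteria at admission, hourly (jittered) analyte trajectories
# that cross the resolution criteria at a sampled hour, an FRIII prescription
# at weight/10 times a sampled adherence factor, fluid records totalling the
# recommended volume times a sampled factor, monitoring reading counts chosen
# to land inside or outside the 80-120% band exactly as drawn, and optional
# complication excursions. The truth table records the realised per-episode
# scores and flags, so pipeline recovery can be checked to the digit.

.parse_quarter <- function(q) {
  m <- regmatches(q, regexec("^([0-9]{4})-Q([1-4])$", q))[[1]]
  if (length(m) != 3L) .abort_config(sprintf("Bad quarter label: '%s'", q))
  c(year = as.integer(m[2]), q = as.integer(m[3]))
}

.quarter_start <- function(q) {
  p <- .parse_quarter(q)
  .parse_minute(sprintf("%d-%02d-01T00:00", p["year"], (p["q"] - 1L) * 3L + 1L))
}

.next_quarter <- function(q) {
  p <- .parse_quarter(q)
  if (p["q"] == 4L) sprintf("%d-Q1", p["year"] + 1L) else
    sprintf("%d-Q%d", p["year"], p["q"] + 1L)
}

.quarter_seq <- function(from, to) {
  .parse_quarter(to)
  out <- from
  while (out[length(out)] != to) {
    nxt <- .next_quarter(out[length(out)])
    out <- c(out, nxt)
    if (length(out) > 400L) .abort_config("Quarter range too long.")
  }
  out
}

.lnorm_pars <- function(median, q1, q3) {
  if (!(q1 < median && median < q3) || q1 <= 0) {
    .abort_config("Need 0 < q1 < median < q3 for a lognormal fit.")
  }
  list(meanlog = log(median),
       sdlog = (log(q3) - log(q1)) / (2 * stats::qnorm(0.75)))
}

#' Default hospital layout
#'
#' Eleven hospitals (A-K) with staggered onboarding — three from 2020, two
#' from 2021, six from 2022 — and per-quarter Poisson episode intensities
#' sized so each hospital's expected episode total over its active quarters
#' matches a realistic multi-hospital registry (about 2,000 episodes over
#' three years).
#'
#' @return Tibble with `code`, `onboard_quarter`, `episodes_per_quarter`,
#'   `poisson`.
#' @export
default_hospitals <- function() {
  tibble::tibble(
    code = LETTERS[1:11],
    onboard_quarter = c(rep("2020-Q1", 3), rep("2021-Q1", 2),
                        rep("2022-Q1", 6)),
    episodes_per_quarter = c(43, 18, 12, 20, 17, 57, 8, 27, 47, 31, 33),
    poisson = TRUE
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic cohort. Defaults describe a three-year,
#' eleven-hospital audit: age median 45 (IQR 29-61) years, 1.29 men per
#' woman, weights lognormal with mean 80 kg and SD 18 kg, DKA duration
#' median 15 h (IQR 9-26), length of stay median 3.3 d (IQR 1.7-6.3), and
#' per-indicator in-band probabilities and complication rates in the ranges
#' seen in multi-centre DKA audits.
#'
#' @param seed Integer seed; identical seed and config give byte-identical
#'   cohorts.
#' @param hospitals Data frame like [default_hospitals()]; `poisson = TRUE`
#'   draws quarterly counts as Poisson(`episodes_per_quarter`), otherwise the
#'   count is fixed.
#' @param end_quarter Last simulated quarter (`"YYYY-Qn"`).
#' @param weight_mean_kg,weight_sd_kg Weight distribution (lognormal, moment
#'   matched).
#' @param target_in_band Named per-indicator probabilities (`frii`, `fluid`,
#'   `glucose`, `ketone`) of an episode being generated inside the 80-120%
#'   band.
#' @param off_band_spread Width of the extra multiplicative deviation beyond
#'   the band edge for off-band episodes (uniform on (0, `off_band_spread`)).
#' @param complication_rates Named probabilities (`hypoglycaemia`,
#'   `hypokalaemia`, `hyperkalaemia`) of injecting a qualifying excursion.
#' @param duration_median_h,duration_iqr_h DKA duration distribution
#'   (lognormal via quantile matching); the median must be at least 5 h so
#'   the two-consecutive-readings resolution rule and exact band labels are
#'   constructible, and individual draws are clamped to \[5, 120\] h.
#' @param los_median_d,los_iqr_d Length-of-stay distribution (lognormal via
#'   quantile matching).
#' @param age_median,age_iqr Age distribution (lognormal via quantile
#'   matching), truncated below at 16 years.
#' @param sex_ratio_men_per_woman Expected men per woman.
#' @param t1dm_fraction,t2dm_fraction Diabetes-type mix (remainder
#'   `"unknown"`).
#' @param history_fraction Probability of a documented diabetes history.
#' @param miscoded_fraction Probability an episode's discharge code is not a
#'   DKA ICD-10 code, exercising the FRIII-list screening arm.
#' @param reading_interval_jitter_min Uniform jitter (minutes, at most 7) on
#'   hourly reading times; capped so the resolution pair stays within the
#'   60 +/- 15 min tolerance and band labels stay exact.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       hospitals = default_hospitals(),
                       end_quarter = "2022-Q4",
                       weight_mean_kg = 80, weight_sd_kg = 18,
                       target_in_band = c(frii = 0.85, fluid = 0.35,
                                          glucose = 0.35, ketone = 0.50),
                       off_band_spread = 0.5,
                       complication_rates = c(hypoglycaemia = 0.08,
                                              hypokalaemia = 0.25,
                                              hyperkalaemia = 0.10),
                       duration_median_h = 15, duration_iqr_h = c(9, 26),
                       los_median_d = 3.3, los_iqr_d = c(1.7, 6.3),
                       age_median = 45, age_iqr = c(29, 61),
                       sex_ratio_men_per_woman = 1.29,
                       t1dm_fraction = 0.70, t2dm_fraction = 0.25,
                       history_fraction = 0.90,
                       miscoded_fraction = 0.05,
                       reading_interval_jitter_min = 5L) {
  hospitals <- tibble::as_tibble(hospitals)
  if (!"poisson" %in% names(hospitals)) hospitals$poisson <- TRUE
  need <- c("code", "onboard_quarter", "episodes_per_quarter", "poisson")
  if (!all(need %in% names(hospitals))) {
    .abort_config(sprintf("`hospitals` needs columns: %s",
                          paste(need, collapse = ", ")))
  }
  probs <- c(target_in_band, complication_rates,
             t1dm_fraction, t2dm_fraction, history_fraction, miscoded_fraction)
  if (any(probs < 0 | probs > 1)) {
    .abort_config("All probabilities must lie in [0, 1].")
  }
  if (!all(c("frii", "fluid", "glucose", "ketone") %in% names(target_in_band))) {
    .abort_config("`target_in_band` must name frii, fluid, glucose, ketone.")
  }
  if (!all(.COMPLICATIONS %in% names(complication_rates))) {
    .abort_config("`complication_rates` must name hypoglycaemia, hypokalaemia, hyperkalaemia.")
  }
  if (duration_median_h < 5) {
    .abort_config(paste(
      "`duration_median_h` must be at least 5 h: shorter episodes cannot",
      "carry the two-consecutive-readings resolution pair together with",
      "exact off-band monitoring counts."))
  }
  if (reading_interval_jitter_min < 0 || reading_interval_jitter_min > 7) {
    .abort_config("`reading_interval_jitter_min` must lie in [0, 7] minutes.")
  }
  if (t1dm_fraction + t2dm_fraction > 1) {
    .abort_config("Diabetes-type fractions must sum to at most 1.")
  }
  cfg <- list(
    seed = as.integer(seed), hospitals = hospitals, end_quarter = end_quarter,
    weight_mean_kg = weight_mean_kg, weight_sd_kg = weight_sd_kg,
    target_in_band = target_in_band, off_band_spread = off_band_spread,
    complication_rates = complication_rates,
    duration_median_h = duration_median_h, duration_iqr_h = duration_iqr_h,
    los_median_d = los_median_d, los_iqr_d = los_iqr_d,
    age_median = age_median, age_iqr = age_iqr,
    sex_ratio_men_per_woman = sex_ratio_men_per_woman,
    t1dm_fraction = t1dm_fraction, t2dm_fraction = t2dm_fraction,
    history_fraction = history_fraction,
    miscoded_fraction = miscoded_fraction,
    reading_interval_jitter_min = as.integer(reading_interval_jitter_min)
  )
  # validate the distribution parameterisations up front
  .lnorm_pars(duration_median_h, duration_iqr_h[1], duration_iqr_h[2])
  .lnorm_pars(los_median_d, los_iqr_d[1], los_iqr_d[2])
  .lnorm_pars(age_median, age_iqr[1], age_iqr[2])
  structure(cfg, class = "sim_config")
}

# adherence factor: exactly 1 when in band, otherwise pushed beyond the band
# edge by a uniform excess so the band label is unambiguous
.band_factor <- function(in_band, spread) {
  if (in_band) return(1)
  side <- sample(c(-1, 1), 1)
  f <- 1 + side * (0.22 + stats::runif(1, 0, spread))
  max(f, 0.05)
}

.jitter <- function(j) if (j == 0L) 0L else sample(seq(-j, j), 1L)

# number of monitoring readings giving an in-band (n = H) or decisively
# off-band count for an integer duration H; minimum counts keep the panel
# constructible (ketones need readings at hours 0, H-1 and H)
.monitoring_n <- function(in_band, f, H, min_n) {
  if (in_band) return(H)
  if (f < 1) {
    max(min_n, min(round(f * H), ceiling(0.8 * H) - 1L))
  } else {
    min(max(floor(1.2 * H) + 1L, round(f * H)), 2L * H - 1L)
  }
}

# reading times (minutes from admission) for one analyte: hourly anchors in
# order, then half-hour slots once anchors are exhausted
.reading_offsets <- function(n, H, anchors_min, halves_min, base_idx) {
  take <- unique(c(base_idx, seq_len(H + 1L)))
  offs <- anchors_min[take[seq_len(min(n, length(take)))]]
  if (n > length(take)) {
    offs <- c(offs, halves_min[seq_len(n - length(take))])
  }
  sort(offs)
}

.gen_episode <- function(code, hospital, quarter, cfg, pars, schedule) {
  q_start <- .quarter_start(quarter)
  q_end <- .quarter_start(.next_quarter(quarter))
  q_minutes <- as.numeric(difftime(q_end, q_start, units = "mins"))
  admission <- q_start + 60 * floor(stats::runif(1, 0, q_minutes - 1))

  age <- max(16L, as.integer(round(stats::rlnorm(1, pars$age$meanlog,
                                                 pars$age$sdlog))))
  sex <- if (stats::runif(1) < cfg$sex_ratio_men_per_woman /
             (1 + cfg$sex_ratio_men_per_woman)) "male" else "female"
  u <- stats::runif(1)
  diabetes_type <- if (u < cfg$t1dm_fraction) "t1dm" else
    if (u < cfg$t1dm_fraction + cfg$t2dm_fraction) "t2dm" else "unknown"
  has_history <- stats::runif(1) < cfg$history_fraction
  weight <- round(stats::rlnorm(1, pars$weight$meanlog, pars$weight$sdlog), 1)

  H <- as.integer(min(max(round(stats::rlnorm(1, pars$dur$meanlog,
                                              pars$dur$sdlog)), 5), 120))
  j <- cfg$reading_interval_jitter_min
  anchors_min <- vapply(0:H, function(k) {
    if (k == 0L) 0L else k * 60L + .jitter(j)
  }, integer(1))
  halves_min <- if (H >= 3L) {
    vapply(0:(H - 3L), function(k) {
      as.integer((k + 0.5) * 60) + .jitter(j)
    }, integer(1))
  } else integer(0)
  dur_h <- anchors_min[H + 1L] / 60
  resolution <- admission + 60 * anchors_min[H + 1L]

  in_band <- vapply(c("frii", "fluid", "glucose", "ketone"), function(i) {
    stats::runif(1) < cfg$target_in_band[[i]]
  }, logical(1))
  comps <- vapply(.COMPLICATIONS, function(cpl) {
    stats::runif(1) < cfg$complication_rates[[cpl]]
  }, logical(1))

  f_frii <- .band_factor(in_band[["frii"]], cfg$off_band_spread)
  f_fluid <- .band_factor(in_band[["fluid"]], cfg$off_band_spread)
  f_glu <- .band_factor(in_band[["glucose"]], cfg$off_band_spread)
  f_ket <- .band_factor(in_band[["ketone"]], cfg$off_band_spread)
  n_glu <- .monitoring_n(in_band[["glucose"]], f_glu, H, 2L)
  n_ket <- .monitoring_n(in_band[["ketone"]], f_ket, H, 3L)

  # glucose: high at admission (secures the diagnosis arm), declining; one
  # interior excursion below 4 mmol/L when hypoglycaemia is injected
  g_off <- .reading_offsets(n_glu, H, anchors_min, halves_min, base_idx = 1L)
  g_val <- round(25 - (25 - 9) * g_off / (H * 60), 1)
  if (comps[["hypoglycaemia"]]) {
    g_val[ceiling((n_glu + 1) / 2)] <- 3.2
  }

  # ketones: >3 at admission, >=0.9 until hour H-2, <0.6 at hours H-1 and H
  ket_base <- c(1L, H, H + 1L)  # anchor indices of hours 0, H-1, H
  k_off <- .reading_offsets(n_ket, H - 2L, anchors_min, halves_min,
                            base_idx = ket_base)
  k_val <- vapply(k_off, function(t) {
    if (t >= anchors_min[H]) 0.3 else
      round(max(0.9, 5.8 - (5.8 - 0.9) * t / max((H - 2) * 60, 1)), 1)
  }, numeric(1))

  # acid-base at every anchor: acidotic until hour H-2, normalised after
  k_idx <- 0:H
  ph_val <- ifelse(k_idx >= H - 1L, 7.36,
                   round(pmin(7.05 + 0.23 * k_idx / max(H - 2L, 1L), 7.28), 2))
  bic_val <- ifelse(k_idx >= H - 1L, 22,
                    round(pmin(10 + 4 * k_idx / max(H - 2L, 1L), 14), 1))

  pot_off <- c(anchors_min[1L], anchors_min[H])
  pot_val <- c(4.3, 4.2)
  if (comps[["hypokalaemia"]]) {
    pot_off <- c(pot_off, anchors_min[2L]); pot_val <- c(pot_val, 3.0)
  }
  if (comps[["hyperkalaemia"]]) {
    pot_off <- c(pot_off, anchors_min[4L]); pot_val <- c(pot_val, 5.9)
  }

  obs <- tibble::tibble(
    episode_code = code,
    timestamp = admission + 60 * c(g_off, k_off, anchors_min, anchors_min,
                                   pot_off, 0L),
    analyte = c(rep("glucose", length(g_off)), rep("ketones", length(k_off)),
                rep("ph", H + 1L), rep("bicarbonate", H + 1L),
                rep("potassium", length(pot_off)), "sbp"),
    value = c(g_val, k_val, ph_val, bic_val, pot_val, 105)
  )

  frii_rate <- 0.1 * weight * f_frii
  rec_l <- recommended_fluid_volume(dur_h, schedule)
  total_ml <- rec_l * 1000 * f_fluid
  if (total_ml <= 1000) {
    fl_vol <- total_ml
    fl_off <- 0L
  } else {
    n_bags <- ceiling((total_ml - 1000) / 1000)
    fl_vol <- c(1000, rep(1000, n_bags - 1L),
                total_ml - 1000 - 1000 * (n_bags - 1L))
    fl_off <- c(0L, pmin(seq_len(n_bags) * 30L, anchors_min[H + 1L] - 5L))
  }
  rx <- tibble::tibble(
    episode_code = code,
    kind = c("frii", rep("fluid", length(fl_off))),
    rate_units_per_h = c(frii_rate, rep(NA_real_, length(fl_off))),
    volume_ml = c(NA_real_, fl_vol),
    start = admission + 60 * c(0L, fl_off)
  )

  los_d <- stats::rlnorm(1, pars$los$meanlog, pars$los$sdlog)
  discharge <- admission + 60 * max(round(los_d * 1440), anchors_min[H + 1L] + 360)
  los_real <- as.numeric(difftime(discharge, admission, units = "days"))

  icd <- if (stats::runif(1) < cfg$miscoded_fraction) "J96.0" else
    switch(diabetes_type, t1dm = "E10.1", t2dm = "E11.1", "E14.1")

  list(
    episode = tibble::tibble(
      episode_code = code, hospital_code = hospital, age_years = age,
      sex = sex, diabetes_type = diabetes_type,
      has_diabetes_history = has_history, weight_kg = weight,
      admission = admission, discharge = discharge,
      urine_ketones = FALSE, confirmed = NA
    ),
    observations = obs,
    prescriptions = rx,
    code_row = tibble::tibble(episode_code = code, icd10 = icd),
    truth = tibble::tibble(
      episode_code = code, hospital_code = hospital, quarter = quarter,
      diagnosis_time = admission, resolution_time = resolution,
      duration_h = dur_h, los_d = los_real,
      frii_pct = f_frii * 100, frii_in_band = in_band[["frii"]],
      fluid_pct = f_fluid * 100, fluid_in_band = in_band[["fluid"]],
      glucose_pct = n_glu / dur_h * 100, glucose_in_band = in_band[["glucose"]],
      ketone_pct = n_ket / dur_h * 100, ketone_in_band = in_band[["ketone"]],
      hypoglycaemia = comps[["hypoglycaemia"]],
      hypokalaemia = comps[["hypokalaemia"]],
      hyperkalaemia = comps[["hyperkalaemia"]]
    )
  )
}

#' Generate a synthetic multi-hospital DKA cohort
#'
#' Draws episodes for every hospital-quarter after onboarding and returns the
#' cohort together with a ground-truth table of the realised per-episode
#' adherence scores, band labels, complication flags and durations. The
#' construction guarantees that every episode passes cohort validation,
#' meets the diagnostic criteria at admission, and resolves at the sampled
#' hour, so [dka_pipeline()] recovers the truth table exactly (durations to
#' the minute even under reading-time jitter).
#'
#' @param config A [sim_config()].
#' @return A list of class `dka_sim` with elements `cohort` (a
#'   [dka_cohort()]) and `truth` (a tibble).
#' @export
#' @examples
#' sim <- generate_cohort(sim_config(
#'   seed = 7,
#'   hospitals = data.frame(code = "A", onboard_quarter = "2022-Q1",
#'                          episodes_per_quarter = 4, poisson = FALSE),
#'   end_quarter = "2022-Q2"
#' ))
#' sim$truth[, c("episode_code", "frii_pct", "frii_in_band")]
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    .abort_config("`config` must be built with sim_config().")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed)

  pars <- list(
    dur = .lnorm_pars(config$duration_median_h, config$duration_iqr_h[1],
                      config$duration_iqr_h[2]),
    los = .lnorm_pars(config$los_median_d, config$los_iqr_d[1],
                      config$los_iqr_d[2]),
    age = .lnorm_pars(config$age_median, config$age_iqr[1],
                      config$age_iqr[2]),
    weight = local({
      m <- config$weight_mean_kg; s <- config$weight_sd_kg
      list(meanlog = log(m^2 / sqrt(m^2 + s^2)),
           sdlog = sqrt(log(1 + s^2 / m^2)))
    })
  )
  schedule <- fluid_schedule()

  episodes <- list(); observations <- list(); prescriptions <- list()
  codes <- list(); truth <- list()
  for (hi in seq_len(nrow(config$hospitals))) {
    h <- config$hospitals[hi, ]
    quarters <- .quarter_seq(h$onboard_quarter, config$end_quarter)
    counter <- 0L
    for (q in quarters) {
      n_q <- if (isTRUE(h$poisson)) stats::rpois(1, h$episodes_per_quarter)
        else as.integer(h$episodes_per_quarter)
      for (i in seq_len(n_q)) {
        counter <- counter + 1L
        code <- sprintf("%s-%05d", h$code, counter)
        g <- .gen_episode(code, h$code, q, config, pars, schedule)
        episodes[[code]] <- g$episode
        observations[[code]] <- g$observations
        prescriptions[[code]] <- g$prescriptions
        codes[[code]] <- g$code_row
        truth[[code]] <- g$truth
      }
    }
  }
  cohort <- dka_cohort(
    dplyr::bind_rows(episodes), dplyr::bind_rows(observations),
    dplyr::bind_rows(prescriptions), dplyr::bind_rows(codes)
  )
  structure(list(cohort = cohort, truth = dplyr::bind_rows(truth)),
            class = "dka_sim")
}

#' @export
print.dka_sim <- function(x, ...) {
  cat("<dka_sim>\n")
  print(x$cohort)
  cat(sprintf("  truth table: %d rows\n", nrow(x$truth)))
  invisible(x)
}

#' Compare pipeline outputs with the simulation truth table
#'
#' Per-indicator comparison of the generated versus pipeline-recovered
#' in-band proportions and flags, per-episode comparison of injected versus
#' detected complications, and the maximum absolute discrepancy in DKA
#' duration.
#'
#' @param sim A `dka_sim` from [generate_cohort()] (or its truth tibble).
#' @param scores A `dka_scores` from [dka_pipeline()] run on the matching
#'   cohort.
#' @return A list of class `dka_recovery`: tibbles `indicators` and
#'   `complications` (truth vs pipeline proportions, mismatch counts),
#'   `max_duration_diff_h`, `max_pct_diff`.
#' @export
truth_compare <- function(sim, scores) {
  truth <- if (inherits(sim, "dka_sim")) sim$truth else sim
  adh <- scores$adherence
  if (!setequal(truth$episode_code, adh$episode_code)) {
    .abort_domain("Truth table and pipeline outputs cover different episode sets.")
  }
  idx <- match(truth$episode_code, adh$episode_code)
  indicators <- dplyr::bind_rows(lapply(c("frii", "fluid", "glucose", "ketone"),
    function(ind) {
      t_band <- truth[[paste0(ind, "_in_band")]]
      p_band <- adh[[paste0(ind, "_in_band")]][idx]
      t_pct <- truth[[paste0(ind, "_pct")]]
      p_pct <- adh[[paste0(ind, "_pct")]][idx]
      tibble::tibble(
        indicator = ind,
        truth_prop = mean(t_band),
        pipeline_prop = mean(p_band, na.rm = TRUE),
        label_mismatches = sum(t_band != p_band, na.rm = TRUE) +
          sum(is.na(p_band)),
        max_abs_pct_diff = max(abs(t_pct - p_pct), na.rm = TRUE)
      )
    }))
  cidx <- match(truth$episode_code, scores$complications$episode_code)
  complications <- dplyr::bind_rows(lapply(.COMPLICATIONS, function(cp) {
    t_f <- truth[[cp]]
    p_f <- scores$complications[[cp]][cidx]
    tibble::tibble(
      complication = cp,
      truth_prop = mean(t_f),
      pipeline_prop = mean(p_f, na.rm = TRUE),
      flag_mismatches = sum(t_f != p_f, na.rm = TRUE) + sum(is.na(p_f))
    )
  }))
  widx <- match(truth$episode_code, scores$windows$episode_code)
  dur_diff <- abs(truth$duration_h - scores$windows$dka_duration_h[widx])
  structure(
    list(
      indicators = indicators,
      complications = complications,
      max_duration_diff_h = if (all(is.na(dur_diff))) NA_real_ else
        max(dur_diff, na.rm = TRUE),
      max_pct_diff = max(indicators$max_abs_pct_diff)
    ),
    class = "dka_recovery"
  )
}

#' @export
print.dka_recovery <- function(x, ...) {
  cat("<dka_recovery>\n")
  print(x$indicators)
  print(x$complications)
  cat(sprintf("  max |duration diff| = %.4g h\n", x$max_duration_diff_h))
  invisible(x)
}
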