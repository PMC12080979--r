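# Screening, diagnosis and resolution detection, and DKA duration.

th <- dka_thresholds()

test_that("screening unions the code list with FRIII-treated episodes", {
  codes <- tibble::tibble(episode_code = c("ep1", "ep3"),
                          icd10 = c("E10.1", "I21.0"))
  expect_equal(screen_candidates(codes, frii_treated = "ep2"),
               c("ep1", "ep2"))
  expect_equal(screen_candidates(codes, frii_treated = "ep1"), "ep1")
  expect_equal(
    screen_candidates(tibble::tibble(episode_code = "ep3", icd10 = "I21.0")),
    character(0)
  )
  # every listed DKA code screens in
  for (code in dka_icd10_codes()) {
    expect_equal(
      screen_candidates(tibble::tibble(episode_code = "x", icd10 = code)),
      "x", info = code)
  }
})

test_that("diagnostic criteria combine the three arms as specified", {
  at <- tmin("2022-01-01T10:00")
  obs1 <- dplyr::bind_rows(
    obs_tbl("2022-01-01T10:00", "glucose", 12.0),
    obs_tbl("2022-01-01T10:00", "ketones", 3.5),
    obs_tbl("2022-01-01T10:00", "ph", 7.25)
  )
  expect_true(meets_dka_criteria(obs1, at, has_history = FALSE, thresholds = th))

  # glucose arm fails without history
  obs2 <- dplyr::bind_rows(
    obs_tbl("2022-01-01T10:00", "glucose", 10.0),
    obs_tbl("2022-01-01T10:00", "ketones", 4.0),
    obs_tbl("2022-01-01T10:00", "ph", 7.2)
  )
  expect_false(meets_dka_criteria(obs2, at, has_history = FALSE, thresholds = th))

  # history substitutes for glucose; bicarbonate substitutes for pH
  obs3 <- dplyr::bind_rows(
    obs_tbl("2022-01-01T10:00", "glucose", 9.0),
    obs_tbl("2022-01-01T10:00", "ketones", 3.2),
    obs_tbl("2022-01-01T10:00", "bicarbonate", 14.0),
    obs_tbl("2022-01-01T10:00", "ph", 7.35)
  )
  expect_true(meets_dka_criteria(obs3, at, has_history = TRUE, thresholds = th))

  # urine ketones >= ++ stand in for the blood-ketone arm of diagnosis
  obs4 <- dplyr::bind_rows(
    obs_tbl("2022-01-01T10:00", "glucose", 15.0),
    obs_tbl("2022-01-01T10:00", "ph", 7.2)
  )
  expect_true(meets_dka_criteria(obs4, at, urine_ketones = TRUE, thresholds = th))

  # missing ketone / acid-base data is indeterminate, not FALSE
  expect_identical(meets_dka_criteria(obs4, at, thresholds = th), NA)
  obs5 <- dplyr::bind_rows(
    obs_tbl("2022-01-01T10:00", "glucose", 15.0),
    obs_tbl("2022-01-01T10:00", "ketones", 4.0)
  )
  expect_identical(meets_dka_criteria(obs5, at, thresholds = th), NA)

  # readings older than the lookback are stale
  obs6 <- dplyr::bind_rows(
    obs_tbl("2022-01-01T01:00", "glucose", 20.0),
    obs_tbl("2022-01-01T10:00", "ketones", 4.0),
    obs_tbl("2022-01-01T10:00", "ph", 7.1)
  )
  expect_false(meets_dka_criteria(obs6, at, has_history = FALSE, thresholds = th))
})

test_that("diagnosis is the earliest qualifying timestamp", {
  # criteria first complete at the third reading time
  obs <- dplyr::bind_rows(
    obs_tbl("2022-01-01T08:00", "glucose", 20),
    obs_tbl("2022-01-01T09:00", "ketones", 4.0),
    obs_tbl("2022-01-01T10:00", "ph", 7.1)
  )
  expect_equal(detect_diagnosis(obs, thresholds = th), tmin("2022-01-01T10:00"))
  expect_equal(oracle_diagnosis(obs, FALSE, th), tmin("2022-01-01T10:00"))

  # satisfied at the first reading
  obs_first <- dplyr::bind_rows(
    obs_tbl(rep("2022-01-01T08:00", 3), c("glucose", "ketones", "ph"),
            c(20, 4.0, 7.1))
  )
  expect_equal(detect_diagnosis(obs_first, thresholds = th),
               tmin("2022-01-01T08:00"))

  # never satisfied
  obs_never <- dplyr::bind_rows(
    obs_tbl(rep("2022-01-01T08:00", 3), c("glucose", "ketones", "ph"),
            c(20, 2.0, 7.1))
  )
  expect_true(is.na(detect_diagnosis(obs_never, thresholds = th)))

  # zero observations: indeterminate with a warning
  expect_warning(
    out <- detect_diagnosis(obs[0, ], thresholds = th),
    class = "dkaudit_no_observations"
  )
  expect_true(is.na(out))
})

test_that("resolution needs a sustained pair and stamps its second reading", {
  diag <- tmin("2022-01-01T08:00")
  base <- dplyr::bind_rows(
    obs_tbl(rep("2022-01-01T08:00", 3), c("glucose", "ketones", "ph"),
            c(20, 4.0, 7.1))
  )
  qualifying <- function(times) {
    dplyr::bind_rows(
      obs_tbl(times, "ph", rep(7.38, length(times))),
      obs_tbl(times, "ketones", rep(0.3, length(times)))
    )
  }
  obs <- dplyr::bind_rows(base, qualifying(c("2022-01-01T14:00",
                                             "2022-01-01T15:00")))
  expect_equal(detect_resolution(obs, diag, th), tmin("2022-01-01T15:00"))
  expect_equal(oracle_resolution(obs, diag, th), tmin("2022-01-01T15:00"))

  # a relapse between qualifying readings forces a later pair
  obs_rel <- dplyr::bind_rows(
    base,
    qualifying("2022-01-01T12:00"),
    obs_tbl("2022-01-01T13:00", "ketones", 1.2),
    obs_tbl("2022-01-01T13:00", "ph", 7.38),
    qualifying(c("2022-01-01T16:00", "2022-01-01T17:00"))
  )
  expect_equal(detect_resolution(obs_rel, diag, th), tmin("2022-01-01T17:00"))
  expect_equal(oracle_resolution(obs_rel, diag, th), tmin("2022-01-01T17:00"))

  # biochemistry never normalises
  obs_never <- dplyr::bind_rows(base, obs_tbl("2022-01-01T14:00", "ph", 7.2))
  expect_true(is.na(detect_resolution(obs_never, diag, th)))

  # readings outside the 60 +/- 15 min gap do not pair
  obs_far <- dplyr::bind_rows(base, qualifying(c("2022-01-01T14:00",
                                                 "2022-01-01T16:00")))
  expect_true(is.na(detect_resolution(obs_far, diag, th)))

  # the mark is configurable to the first reading of the pair
  th_first <- dka_thresholds(res_mark = "first")
  expect_equal(detect_resolution(obs, diag, th_first), tmin("2022-01-01T14:00"))

  # diagnosis after the last observation: indeterminate with a warning
  expect_warning(
    out <- detect_resolution(base, tmin("2022-01-02T08:00"), th),
    class = "dkaudit_no_post_diagnosis"
  )
  expect_true(is.na(out))
})

test_that("detectors match brute-force scans on random episodes and thresholds", {
  set.seed(41)
  for (i in 1:150) {
    obs <- random_episode_obs()
    thr <- if (i %% 3 == 0) random_thresholds() else th
    history <- i %% 2 == 0
    diag <- suppressWarnings(detect_diagnosis(obs, history, thresholds = thr))
    expect_equal(diag, oracle_diagnosis(obs, history, thr))
    if (!is.na(diag)) {
      res <- suppressWarnings(detect_resolution(obs, diag, thr))
      expect_equal(res, oracle_resolution(obs, diag, thr))
    }
  }
})

test_that("tightening the resolution ketone threshold never hastens resolution", {
  # crafted episode: ketones 0.9 at 14:00/15:00 qualify only under the loose
  # threshold; 0.3 at 16:00/17:00 qualify under both
  diag <- tmin("2022-01-01T08:00")
  crafted <- dplyr::bind_rows(
    obs_tbl(rep("2022-01-01T08:00", 3), c("glucose", "ketones", "ph"),
            c(20, 4.0, 7.1)),
    obs_tbl(c("2022-01-01T14:00", "2022-01-01T15:00",
              "2022-01-01T16:00", "2022-01-01T17:00"), "ketones",
            c(0.9, 0.9, 0.3, 0.3)),
    obs_tbl(c("2022-01-01T14:00", "2022-01-01T15:00",
              "2022-01-01T16:00", "2022-01-01T17:00"), "ph", rep(7.38, 4))
  )
  res_loose <- detect_resolution(crafted, diag,
                                 dka_thresholds(res_ketones = 1.0))
  res_tight <- detect_resolution(crafted, diag,
                                 dka_thresholds(res_ketones = 0.4))
  expect_equal(res_loose, tmin("2022-01-01T15:00"))
  expect_equal(res_tight, tmin("2022-01-01T17:00"))
  expect_true(res_tight >= res_loose)

  set.seed(57)
  for (i in 1:40) {
    obs <- random_episode_obs()
    diag <- suppressWarnings(detect_diagnosis(obs, TRUE))
    if (is.na(diag)) next
    res_loose <- suppressWarnings(
      detect_resolution(obs, diag, dka_thresholds(res_ketones = 1.0)))
    res_tight <- suppressWarnings(
      detect_resolution(obs, diag, dka_thresholds(res_ketones = 0.4)))
    if (!is.na(res_tight)) {
      expect_false(is.na(res_loose))
      expect_true(res_tight >= res_loose)
    }
  }
})

test_that("durations are non-negative and invariant under time translation", {
  expect_equal(
    dka_duration_hours(tmin("2022-01-01T10:00"), tmin("2022-01-01T15:00")), 5)
  expect_equal(
    dka_duration_hours(tmin("2022-01-01T22:30"), tmin("2022-01-02T08:18")), 9.8)
  expect_equal(
    dka_duration_hours(tmin("2022-01-01T10:00"), tmin("2022-01-01T10:00")), 0)

  set.seed(5)
  for (i in 1:20) {
    obs <- random_episode_obs()
    shift <- sample(1:5000, 1) * 60
    obs2 <- obs
    obs2$timestamp <- obs$timestamp + shift
    d1 <- suppressWarnings(detect_diagnosis(obs, TRUE))
    d2 <- suppressWarnings(detect_diagnosis(obs2, TRUE))
    if (is.na(d1)) {
      expect_true(is.na(d2))
      next
    }
    expect_equal(d2, d1 + shift)
    r1 <- suppressWarnings(detect_resolution(obs, d1))
    r2 <- suppressWarnings(detect_resolution(obs2, d2))
    if (!is.na(r1)) {
      expect_equal(dka_duration_hours(d2, r2), dka_duration_hours(d1, r1))
      expect_true(dka_duration_hours(d1, r1) >= 0)
    }
  }
})

test_that("cohort windows honour the manual confirmation override", {
  cohort <- adherent_cohort()
  w <- ascertain_windows(cohort)
  expect_equal(w$diagnosis_time, tmin("2022-01-01T08:00"))
  expect_equal(w$resolution_time, tmin("2022-01-01T13:00"))
  expect_true(w$resolved)
  expect_equal(w$dka_duration_h, 5)

  cohort$episodes$confirmed <- FALSE
  w2 <- ascertain_windows(cohort)
  expect_true(is.na(w2$diagnosis_time))
  expect_false(w2$resolved)
})
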