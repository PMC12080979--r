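# Adherence formulas, the fluid schedule, banding and per-episode scoring.

test_that("FRIII adherence reproduces the guideline worked example", {
  expect_equal(frii_adherence(7.0, 70), 100)
  expect_equal(frii_adherence(3.5, 70), 50)
  expect_equal(frii_adherence(14.0, 70), 200)
  expect_equal(frii_adherence(0, 55), 0)
  expect_error(frii_adherence(5, 0), class = "dkaudit_domain_error")
  expect_error(frii_adherence(-1, 70), class = "dkaudit_domain_error")
})

test_that("FRIII adherence is linear in rate and inverse in weight", {
  set.seed(12)
  for (i in 1:25) {
    r <- runif(1, 0.5, 20)
    w <- runif(1, 40, 160)
    expect_equal(frii_adherence(2 * r, w), 2 * frii_adherence(r, w))
    expect_equal(frii_adherence(r, 2 * w), frii_adherence(r, w) / 2)
    expect_equal(frii_adherence(0.1 * w, w), 100)
  }
})

test_that("the fluid schedule accrues whole bags at their completion times", {
  sched <- fluid_schedule()
  # bolus 1 L; bags complete at 1, 3, 5, 9, 13, 19 h; continuation every 6 h
  expect_equal(recommended_fluid_volume(0, sched), 1)
  expect_equal(recommended_fluid_volume(1, sched), 2)
  expect_equal(recommended_fluid_volume(5, sched), 4)
  expect_equal(recommended_fluid_volume(13, sched), 6)
  expect_equal(recommended_fluid_volume(19, sched), 7)
  expect_equal(recommended_fluid_volume(25, sched), 8)
  # just before a boundary the earlier value still holds
  expect_equal(recommended_fluid_volume(4.99, sched), 3)
  expect_error(recommended_fluid_volume(-1, sched),
               class = "dkaudit_domain_error")
})

test_that("whole-bag accrual matches a cumulative-sum oracle at boundaries", {
  sched <- fluid_schedule()
  ends <- cumsum(sched$bags$over_hours)
  cum_l <- (sched$bolus_ml + cumsum(sched$bags$volume_ml)) / 1000
  for (i in seq_along(ends)) {
    expect_equal(recommended_fluid_volume(ends[i], sched), cum_l[i])
  }
  # non-decreasing, step-valued over a dense grid
  grid <- seq(0, 40, by = 0.25)
  vals <- recommended_fluid_volume(grid, sched)
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals == round(vals)))
})

test_that("pro-rata accrual is continuous, piecewise linear, and agrees at bag ends", {
  sched <- fluid_schedule(accrual = "pro_rata")
  whole <- fluid_schedule()
  ends <- cumsum(whole$bags$over_hours)
  for (e in ends) {
    expect_equal(recommended_fluid_volume(e, sched),
                 recommended_fluid_volume(e, whole))
  }
  # mid-bag: half of the 2 h bag running from 1 h to 3 h
  expect_equal(recommended_fluid_volume(2, sched), 2.5)
  grid <- seq(0, 30, by = 0.1)
  vals <- recommended_fluid_volume(grid, sched)
  expect_true(all(diff(vals) >= 0))
})

test_that("fluid adherence reproduces the guideline worked example", {
  expect_equal(fluid_adherence(3, 5), 75)
  expect_equal(fluid_adherence(5, 5), 125)
  set.seed(31)
  for (d in c(0, runif(10, 0, 40))) {
    expect_equal(fluid_adherence(recommended_fluid_volume(d), d), 100)
  }
})

test_that("monitoring adherence reproduces the guideline worked example", {
  expect_equal(monitoring_adherence(5, 5), 100)
  expect_equal(monitoring_adherence(3, 5), 60)
  expect_equal(monitoring_adherence(7, 5), 140)
  # no truncation above 100%
  expect_equal(monitoring_adherence(20, 5), 400)
  expect_warning(out <- monitoring_adherence(3, 0),
                 class = "dkaudit_zero_duration")
  expect_true(is.na(out))
})

test_that("the adherence band is inclusive at both ends", {
  th <- dka_thresholds()
  expect_true(within_band(100, th))
  expect_true(within_band(80, th))
  expect_true(within_band(120, th))
  expect_false(within_band(79.9, th))
  expect_false(within_band(120.1, th))
})

test_that("banding at full precision matches banding the rounded score away from bounds", {
  set.seed(77)
  th <- dka_thresholds()
  pct <- runif(400, 0, 200)
  away <- abs(pct - 80) > 0.05 & abs(pct - 120) > 0.05
  expect_equal(within_band(pct[away], th), within_band(round(pct[away], 1), th))
})

test_that("a fully adherent episode scores 100 on all four indicators", {
  cohort <- adherent_cohort()
  w <- ascertain_windows(cohort)
  a <- score_adherence(cohort, w)
  expect_equal(a$frii_pct, 100)
  expect_equal(a$fluid_pct, 100)
  expect_equal(a$glucose_pct, 100)
  expect_equal(a$ketone_pct, 100)
  expect_true(all(c(a$frii_in_band, a$fluid_in_band, a$glucose_in_band,
                    a$ketone_in_band)))
})

test_that("scoring honours its per-indicator absence contracts", {
  cohort <- adherent_cohort()
  w <- ascertain_windows(cohort)

  # no fluid records: fluid adherence is 0%, not absent
  no_fluid <- cohort
  no_fluid$prescriptions <-
    cohort$prescriptions[cohort$prescriptions$kind != "fluid", ]
  a <- score_adherence(no_fluid, w)
  expect_equal(a$fluid_pct, 0)
  expect_false(a$fluid_in_band)

  # unresolved window: only the FRIII score is present
  w_unres <- w
  w_unres$resolved <- FALSE
  w_unres$resolution_time <- tmin(NA_character_)
  w_unres$dka_duration_h <- NA_real_
  a2 <- score_adherence(cohort, w_unres)
  expect_equal(a2$frii_pct, 100)
  expect_true(is.na(a2$fluid_pct))
  expect_true(is.na(a2$glucose_pct))
  expect_true(is.na(a2$ketone_pct))

  # no FRIII prescription: FRIII score absent
  no_frii <- cohort
  no_frii$prescriptions <-
    cohort$prescriptions[cohort$prescriptions$kind != "frii", ]
  a3 <- score_adherence(no_frii, w)
  expect_true(is.na(a3$frii_pct))
  expect_false(is.na(a3$fluid_pct))

  # missing weight: FRIII score absent with a warning
  no_weight <- cohort
  no_weight$episodes$weight_kg <- NA_real_
  expect_warning(a4 <- score_adherence(no_weight, w),
                 class = "dkaudit_missing_weight")
  expect_true(is.na(a4$frii_pct))
})

test_that("the first FRIII prescription by start time sets the score", {
  cohort <- adherent_cohort()
  extra <- tibble::tibble(
    episode_code = "ep1", kind = "frii", rate_units_per_h = 3.5,
    volume_ml = NA_real_, start = tmin("2022-01-01T09:30")
  )
  cohort$prescriptions <- dplyr::bind_rows(cohort$prescriptions, extra)
  w <- ascertain_windows(cohort)
  a <- score_adherence(cohort, w)
  expect_equal(a$frii_pct, 100)  # the 08:00 rate, not the later 3.5 u/h
})

test_that("duplicate readings at one timestamp count once per analyte", {
  cohort <- adherent_cohort()
  dup <- obs_tbl("2022-01-01T09:00", "glucose", 19.9)
  cohort$observations <- dplyr::bind_rows(cohort$observations, dup)
  cohort <- dka_cohort(cohort$episodes, cohort$observations,
                       cohort$prescriptions, cohort$discharge_codes)
  w <- ascertain_windows(cohort)
  a <- score_adherence(cohort, w)
  expect_equal(a$glucose_pct, 100)
})
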