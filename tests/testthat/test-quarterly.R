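# Quarter assignment, KPI aggregation, chi-square comparisons, reports.

test_that("timestamps map to calendar quarters", {
  expect_equal(quarter_of(tmin("2020-02-15T10:00")), "2020-Q1")
  expect_equal(quarter_of(tmin("2022-12-31T23:59")), "2022-Q4")
  expect_equal(quarter_of(tmin("2021-04-01T00:00")), "2021-Q2")
  expect_equal(quarter_of(tmin(c("2020-01-01T00:00", "2020-03-31T23:59"))),
               c("2020-Q1", "2020-Q1"))
})

test_that("quarter aggregation computes band proportions and SPSS-style quantiles", {
  adh <- tibble::tibble(
    episode_code = sprintf("e%02d", 1:10),
    frii_pct = 100, fluid_pct = 100, glucose_pct = 100, ketone_pct = 100,
    frii_in_band = TRUE,
    fluid_in_band = rep(c(TRUE, FALSE), c(6, 4)),
    glucose_in_band = c(rep(TRUE, 3), rep(FALSE, 5), NA, NA),
    ketone_in_band = TRUE
  )
  flags <- tibble::tibble(
    episode_code = adh$episode_code,
    hypoglycaemia = rep(c(TRUE, FALSE), c(2, 8)),
    hypokalaemia = FALSE, hyperkalaemia = FALSE
  )
  outcomes <- tibble::tibble(
    episode_code = adh$episode_code,
    dka_duration_h = c(4, 6, 8, 10, 12, NA, NA, NA, NA, NA),
    length_of_stay_d = 1:10
  )
  k <- aggregate_quarter(adh, flags, outcomes, "A", "2022-Q1")
  expect_equal(k$n_episodes, 10L)
  expect_equal(k$fluid_in_band_prop, 0.6)
  # absent scores leave that indicator's denominator only
  expect_equal(k$glucose_scored_n, 8L)
  expect_equal(k$glucose_in_band_prop, 3 / 8)
  expect_equal(k$hypoglycaemia_prop, 0.2)
  # durations {4,6,8,10,12}: median 8, IQR (5, 11) under type-6 quantiles
  expect_equal(k$duration_median, 8)
  expect_equal(k$duration_q1, 5)
  expect_equal(k$duration_q3, 11)

  k0 <- aggregate_quarter(adh[0, ], flags[0, ], outcomes[0, ], "A", "2022-Q1")
  expect_equal(k0$n_episodes, 0L)
  expect_true(is.na(k0$fluid_in_band_prop))
  expect_true(is.na(k0$duration_median))
})

test_that("the Pearson statistic matches hand computation and the null case", {
  expect_equal(chi_square_2x2(matrix(c(10, 20, 20, 10), 2))$statistic,
               6.667, tolerance = 1e-3)
  expect_equal(chi_square_2x2(matrix(c(0, 10, 10, 0), 2))$statistic, 20)
  expect_equal(chi_square_2x2(matrix(c(15, 15, 15, 15), 2))$statistic, 0)
  expect_true(chi_square_2x2(matrix(c(1, 40, 0, 40), 2))$unreliable)
})

test_that("the Pearson statistic matches the closed form and chisq.test", {
  set.seed(19)
  for (i in 1:300) {
    tab <- matrix(sample(1:40, 4, replace = TRUE), 2)
    a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
    n <- sum(tab)
    closed <- n * (a * d - b * c_)^2 /
      ((a + b) * (c_ + d) * (a + c_) * (b + d))
    got <- chi_square_2x2(tab)
    expect_equal(got$statistic, closed, tolerance = 1e-9)
    # independent cross-check against the stock implementation
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, unname(ref$p.value))
    ref_y <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    expect_equal(chi_square_2x2(tab, correct = TRUE)$statistic,
                 unname(ref_y$statistic))
  }
})

test_that("first-vs-last comparison picks the data-driven quarters and is symmetric", {
  sim <- small_sim(seed = 29, per_quarter = 12,
                   hospitals = c("A", "B"), onboard = c("2022-Q1", "2022-Q3"))
  scores <- dka_pipeline(sim$cohort)
  kpis <- aggregate_kpis(sim$cohort, scores)

  cmp_a <- first_last_comparison(kpis, "A", "fluid")
  expect_equal(cmp_a$first_quarter, "2022-Q1")
  expect_equal(cmp_a$last_quarter, "2022-Q4")
  # hospital B onboards later: its first quarter reflects its own data
  cmp_b <- first_last_comparison(kpis, "B", "fluid")
  expect_equal(cmp_b$first_quarter, "2022-Q3")

  # swapping first and last quarters leaves the statistic unchanged
  swapped <- kpis
  swapped$quarter[swapped$hospital_code == "A"] <-
    rev(sort(unique(kpis$quarter[kpis$hospital_code == "A"])))[
      match(kpis$quarter[kpis$hospital_code == "A"],
            sort(unique(kpis$quarter[kpis$hospital_code == "A"])))]
  cmp_swapped <- first_last_comparison(swapped, "A", "fluid")
  expect_equal(cmp_swapped$chi_square_statistic, cmp_a$chi_square_statistic)

  expect_error(
    first_last_comparison(kpis[kpis$quarter == "2022-Q4", ], "A", "fluid"),
    class = "dkaudit_domain_error")
})

test_that("pooled KPI rows conserve counts and are the episode-weighted mean", {
  sim <- small_sim(seed = 31, per_quarter = 10)
  scores <- dka_pipeline(sim$cohort)
  kpis <- aggregate_kpis(sim$cohort, scores, pooled = TRUE)
  own <- kpis[kpis$hospital_code != "(all)", ]
  pooled <- kpis[kpis$hospital_code == "(all)", ]
  for (q in unique(pooled$quarter)) {
    p <- pooled[pooled$quarter == q, ]
    h <- own[own$quarter == q, ]
    expect_equal(p$n_episodes, sum(h$n_episodes))
    for (ind in c("frii", "fluid", "glucose", "ketone")) {
      expect_equal(p[[paste0(ind, "_in_band_n")]],
                   sum(h[[paste0(ind, "_in_band_n")]]))
      # pooled proportion = episode-weighted mean of hospital proportions
      wsum <- sum(h[[paste0(ind, "_in_band_prop")]] *
                    h[[paste0(ind, "_scored_n")]])
      expect_equal(p[[paste0(ind, "_in_band_prop")]],
                   wsum / sum(h[[paste0(ind, "_scored_n")]]))
    }
  }
})

test_that("feedback reports are structural, anonymised and deterministic", {
  sim <- small_sim(seed = 37, per_quarter = 9)
  scores <- dka_pipeline(sim$cohort)
  kpis <- aggregate_kpis(sim$cohort, scores, pooled = TRUE)
  cmp <- first_last_comparisons(kpis)

  r1 <- render_feedback(kpis, kpis, cmp, "A")
  r2 <- render_feedback(kpis, kpis, cmp, "A")
  expect_identical(r1, r2)  # byte-identical across runs
  expect_match(r1, "hospital A")
  expect_match(r1, "pooled")
  expect_false(grepl("hospital B", r1))  # peers stay anonymous

  dir <- withr::local_tempdir()
  paths <- write_feedback_reports(kpis, kpis, cmp, dir)
  expect_true(file.exists(file.path(dir, "A.md")))
  expect_true(file.exists(file.path(dir, "B.md")))
  expect_true(file.exists(file.path(dir, "comparisons.csv")))

  # a hospital with a single quarter of data gets no comparison section
  one_q <- kpis[kpis$hospital_code == "A" & kpis$quarter == "2022-Q1", ]
  r_single <- render_feedback(one_q, kpis, cmp[0, ], "A")
  expect_false(grepl("First vs last", r_single))

  expect_error(render_feedback(kpis, kpis, cmp, "Z"),
               class = "dkaudit_domain_error")
})
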