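# Quarterly KPI aggregation, first-vs-last-quarter comparison, and
# anonymised per-hospital feedback reports.

.INDICATORS <- c("frii", "fluid", "glucose", "ketone")
.COMPLICATIONS <- c("hypoglycaemia", "hypokalaemia", "hyperkalaemia")

#' Calendar quarter of a timestamp
#'
#' @param timestamp `POSIXct` (vectorised).
#' @return Labels `"YYYY-Qn"` with Q1 = January-March.
#' @export
#' @examples
#' quarter_of(as.POSIXct("2022-12-31 10:00", tz = "UTC"))
quarter_of <- function(timestamp) {
  lt <- as.POSIXlt(timestamp, tz = "UTC")
  sprintf("%d-Q%d", lt$year + 1900L, lt$mon %/% 3L + 1L)
}

.kpi_row <- function(hospital, quarter, adherence, flags, outcomes,
                     quantile_type = 6) {
  out <- tibble::tibble(hospital_code = hospital, quarter = quarter,
                        n_episodes = nrow(adherence))
  for (ind in .INDICATORS) {
    flag <- adherence[[paste0(ind, "_in_band")]]
    scored <- sum(!is.na(flag))
    n_in <- sum(flag, na.rm = TRUE)
    out[[paste0(ind, "_scored_n")]] <- scored
    out[[paste0(ind, "_in_band_n")]] <- n_in
    out[[paste0(ind, "_in_band_prop")]] <-
      if (scored > 0) n_in / scored else NA_real_
  }
  comp_scored <- sum(!is.na(flags$hypoglycaemia))
  out$comp_scored_n <- comp_scored
  for (cp in .COMPLICATIONS) {
    n_cp <- sum(flags[[cp]], na.rm = TRUE)
    out[[paste0(cp, "_n")]] <- n_cp
    out[[paste0(cp, "_prop")]] <-
      if (comp_scored > 0) n_cp / comp_scored else NA_real_
  }
  dur <- median_iqr(outcomes$dka_duration_h, quantile_type)
  los <- median_iqr(outcomes$length_of_stay_d, quantile_type)
  out$duration_median <- dur$median
  out$duration_q1 <- dur$q1
  out$duration_q3 <- dur$q3
  out$los_median <- los$median
  out$los_q1 <- los$q1
  out$los_q3 <- los$q3
  out
}

#' Aggregate one hospital-quarter into a KPI row
#'
#' Counts and proportions of episodes inside the adherence band for each of
#' the four indicators (episodes with an absent score are excluded from that
#' indicator's denominator only), complication proportions, and median/IQR of
#' DKA duration and length of stay. Unresolved episodes contribute to
#' complication denominators and length of stay, but not to duration medians.
#'
#' @param adherence,flags,outcomes Per-episode tibbles (for this
#'   hospital-quarter only) from [score_adherence()], [complication_flags()]
#'   and [outcome_records()].
#' @param hospital,quarter Labels for the aggregate.
#' @param quantile_type Quantile interpolation rule (see [median_iqr()]).
#' @return One-row KPI tibble.
#' @export
aggregate_quarter <- function(adherence, flags, outcomes, hospital, quarter,
                              quantile_type = 6) {
  .kpi_row(hospital, quarter, adherence, flags, outcomes, quantile_type)
}

#' Aggregate a scored cohort into per-hospital quarterly KPIs
#'
#' Assigns each episode to the calendar quarter of its admission, then
#' aggregates every hospital-quarter with [aggregate_quarter()]. With
#' `pooled = TRUE`, rows for the anonymised pooled peer summary (all
#' hospitals combined, `hospital_code = "(all)"`) are appended, recomputed
#' from the episode level so pooled counts are exactly the sums of the
#' per-hospital counts.
#'
#' @param cohort A `dka_cohort`.
#' @param scores Pipeline result from [dka_pipeline()], or a list with
#'   elements `adherence`, `complications`, `outcomes`.
#' @param pooled Append pooled peer rows?
#' @param quantile_type Quantile interpolation rule (see [median_iqr()]).
#' @return KPI tibble, one row per hospital-quarter (plus pooled rows),
#'   ordered by hospital then quarter.
#' @export
aggregate_kpis <- function(cohort, scores, pooled = FALSE, quantile_type = 6) {
  ep <- cohort$episodes
  key <- tibble::tibble(
    episode_code = ep$episode_code,
    hospital_code = ep$hospital_code,
    quarter = quarter_of(ep$admission)
  )
  groups <- dplyr::distinct(key, .data$hospital_code, .data$quarter)
  groups <- dplyr::arrange(groups, .data$hospital_code, .data$quarter)
  one <- function(h, q) {
    codes <- key$episode_code[key$hospital_code == h & key$quarter == q]
    .kpi_row(h, q,
             scores$adherence[scores$adherence$episode_code %in% codes, ],
             scores$complications[scores$complications$episode_code %in% codes, ],
             scores$outcomes[scores$outcomes$episode_code %in% codes, ],
             quantile_type)
  }
  out <- dplyr::bind_rows(Map(one, groups$hospital_code, groups$quarter))
  if (pooled) {
    pooled_rows <- dplyr::bind_rows(lapply(sort(unique(key$quarter)), function(q) {
      codes <- key$episode_code[key$quarter == q]
      .kpi_row("(all)", q,
               scores$adherence[scores$adherence$episode_code %in% codes, ],
               scores$complications[scores$complications$episode_code %in% codes, ],
               scores$outcomes[scores$outcomes$episode_code %in% codes, ],
               quantile_type)
    }))
    out <- dplyr::bind_rows(out, pooled_rows)
  }
  out
}

#' Pearson chi-square on a 2x2 table
#'
#' Uncorrected Pearson statistic `sum((O - E)^2 / E)` with 1 degree of
#' freedom (Yates continuity correction available as a switch), equal to
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` in closed form. The result is
#' flagged unreliable when any expected cell falls below 1 (the statistic is
#' still returned).
#'
#' @param tab 2x2 numeric matrix of counts.
#' @param correct Apply the Yates continuity correction?
#' @return List with `statistic`, `p_value`, `expected`, `unreliable`.
#' @export
#' @examples
#' chi_square_2x2(matrix(c(10, 20, 20, 10), 2))$statistic  # 6.667
chi_square_2x2 <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0)) {
    .abort_domain("`tab` must be a 2x2 matrix of non-negative counts.")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  dev <- abs(tab - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  statistic <- sum(dev^2 / expected)
  list(
    statistic = statistic,
    p_value = stats::pchisq(statistic, df = 1, lower.tail = FALSE),
    expected = expected,
    unreliable = any(expected < 1)
  )
}

.counts_for_indicator <- function(kpi_row, indicator) {
  if (indicator %in% .INDICATORS) {
    n <- kpi_row[[paste0(indicator, "_scored_n")]]
    x <- kpi_row[[paste0(indicator, "_in_band_n")]]
  } else {
    n <- kpi_row$comp_scored_n
    x <- kpi_row[[paste0(indicator, "_n")]]
  }
  c(x = x, n = n)
}

#' Compare a hospital's first and last audit quarters
#'
#' Pearson chi-square (uncorrected, 1 df) on the 2x2 table of
#' in-band / not-in-band counts (or complication / no-complication counts)
#' in the hospital's first versus last quarter with data. The first quarter
#' is the earliest quarter containing at least one episode for that hospital,
#' accommodating staggered onboarding; the last is the latest.
#'
#' @param kpis KPI tibble from [aggregate_kpis()].
#' @param hospital Hospital code.
#' @param indicator One of `"frii"`, `"fluid"`, `"glucose"`, `"ketone"`,
#'   `"hypoglycaemia"`, `"hypokalaemia"`, `"hyperkalaemia"`.
#' @param correct Apply the Yates continuity correction?
#' @return One-row tibble: `hospital_code`, `indicator`, `first_quarter`,
#'   `last_quarter`, `first_prop`, `last_prop`, `chi_square_statistic`,
#'   `p_value`, `unreliable`.
#' @export
first_last_comparison <- function(kpis, hospital, indicator,
                                  correct = FALSE) {
  indicator <- match.arg(indicator, c(.INDICATORS, .COMPLICATIONS))
  rows <- kpis[kpis$hospital_code == hospital & kpis$n_episodes >= 1, ]
  rows <- rows[order(rows$quarter), ]
  if (nrow(rows) < 2L) {
    .abort_domain(sprintf(
      "Hospital '%s' needs at least two quarters with data for a comparison.",
      hospital))
  }
  first <- rows[1, ]
  last <- rows[nrow(rows), ]
  cf <- .counts_for_indicator(first, indicator)
  cl <- .counts_for_indicator(last, indicator)
  tab <- matrix(c(cf[["x"]], cf[["n"]] - cf[["x"]],
                  cl[["x"]], cl[["n"]] - cl[["x"]]), nrow = 2)
  chi <- chi_square_2x2(tab, correct = correct)
  tibble::tibble(
    hospital_code = hospital, indicator = indicator,
    first_quarter = first$quarter, last_quarter = last$quarter,
    first_prop = if (cf[["n"]] > 0) cf[["x"]] / cf[["n"]] else NA_real_,
    last_prop = if (cl[["n"]] > 0) cl[["x"]] / cl[["n"]] else NA_real_,
    chi_square_statistic = chi$statistic,
    p_value = chi$p_value,
    unreliable = chi$unreliable
  )
}

#' First-vs-last comparisons for every hospital and indicator
#'
#' Runs [first_last_comparison()] across all hospitals in a KPI table (pooled
#' rows excluded) and all adherence and complication indicators, skipping
#' hospitals with fewer than two quarters of data. Raw p-values are reported;
#' an optional multiplicity adjustment ([stats::p.adjust()] method) can be
#' applied.
#'
#' @param kpis KPI tibble from [aggregate_kpis()].
#' @param indicators Indicators to compare.
#' @param correct Apply the Yates continuity correction?
#' @param p_adjust `"none"` (default, matching raw reporting) or any
#'   [stats::p.adjust()] method; adjusted values are added as `p_adjusted`.
#' @return Tibble of comparisons.
#' @export
first_last_comparisons <- function(kpis,
                                   indicators = c(.INDICATORS, .COMPLICATIONS),
                                   correct = FALSE, p_adjust = "none") {
  hospitals <- sort(unique(kpis$hospital_code[kpis$hospital_code != "(all)"]))
  rows <- list()
  for (h in hospitals) {
    if (sum(kpis$hospital_code == h & kpis$n_episodes >= 1) < 2L) next
    for (ind in indicators) {
      rows[[length(rows) + 1L]] <-
        first_last_comparison(kpis, h, ind, correct = correct)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!identical(p_adjust, "none") && nrow(out) > 0) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  }
  out
}

# -- feedback reports ---------------------------------------------------------

.fmt <- function(x, digits = 1) {
  ifelse(is.na(x), "-", formatC(x, format = "f", digits = digits))
}

.md_table <- function(header, rows) {
  c(paste0("| ", paste(header, collapse = " | "), " |"),
    paste0("|", paste(rep("---", length(header)), collapse = "|"), "|"),
    vapply(rows, function(r) paste0("| ", paste(r, collapse = " | "), " |"),
           character(1)))
}

.trend_rows <- function(kpis) {
  lapply(seq_len(nrow(kpis)), function(i) {
    k <- kpis[i, ]
    c(k$quarter, k$n_episodes,
      vapply(.INDICATORS, function(ind) {
        p <- k[[paste0(ind, "_in_band_prop")]]
        if (is.na(p)) "-" else sprintf("%s%% (%d/%d)", .fmt(100 * p, 0),
                                       k[[paste0(ind, "_in_band_n")]],
                                       k[[paste0(ind, "_scored_n")]])
      }, character(1)),
      vapply(.COMPLICATIONS, function(cp) {
        .fmt(100 * k[[paste0(cp, "_prop")]], 0)
      }, character(1)),
      sprintf("%s (%s-%s)", .fmt(k$duration_median), .fmt(k$duration_q1),
              .fmt(k$duration_q3)),
      sprintf("%s (%s-%s)", .fmt(k$los_median), .fmt(k$los_q1),
              .fmt(k$los_q3)))
  })
}

.TREND_HEADER <- c("Quarter", "n", "FRIII in band", "Fluids in band",
                   "Glucose in band", "Ketones in band", "Hypoglycaemia %",
                   "Hypokalaemia %", "Hyperkalaemia %",
                   "DKA duration h, median (IQR)", "Stay d, median (IQR)")

#' Render one hospital's feedback report
#'
#' A deterministic markdown document for one feedback cycle: the hospital's
#' trailing quarters of KPIs (most recent `n_quarters`), the pooled
#' anonymised peer summary over the same quarters, and the first-vs-last
#' quarter comparisons. Hospitals with a single quarter of data get no
#' comparison section.
#'
#' @param kpis KPI tibble from [aggregate_kpis()] (per-hospital rows).
#' @param pooled Pooled KPI rows (`hospital_code == "(all)"`), e.g. from
#'   `aggregate_kpis(..., pooled = TRUE)`.
#' @param comparisons Comparisons tibble from [first_last_comparisons()]
#'   (may be empty).
#' @param hospital Hospital code to report on.
#' @param n_quarters Number of trailing quarters to show.
#' @return The report as a single character string (markdown).
#' @export
render_feedback <- function(kpis, pooled, comparisons, hospital,
                            n_quarters = 4) {
  own <- kpis[kpis$hospital_code == hospital, ]
  if (nrow(own) == 0L) {
    .abort_domain(sprintf("Hospital '%s' is absent from the KPI table.",
                          hospital))
  }
  own <- own[order(own$quarter), ]
  own <- utils::tail(own, n_quarters)
  peer <- pooled[pooled$hospital_code == "(all)" &
                   pooled$quarter %in% own$quarter, ]
  peer <- peer[order(peer$quarter), ]

  lines <- c(
    sprintf("# DKA care feedback — hospital %s", hospital),
    "",
    sprintf("Quarters covered: %s to %s.", own$quarter[1],
            own$quarter[nrow(own)]),
    "",
    "## Your quarterly performance",
    "",
    .md_table(.TREND_HEADER, .trend_rows(own)),
    "",
    "## All participating hospitals (anonymised, pooled)",
    "",
    .md_table(.TREND_HEADER, .trend_rows(peer))
  )
  comp <- comparisons[comparisons$hospital_code == hospital, ]
  if (nrow(comp) > 0L) {
    comp_rows <- lapply(seq_len(nrow(comp)), function(i) {
      r <- comp[i, ]
      c(r$indicator, r$first_quarter, r$last_quarter,
        paste0(.fmt(100 * r$first_prop, 0), "%"),
        paste0(.fmt(100 * r$last_prop, 0), "%"),
        .fmt(r$chi_square_statistic, 3), .fmt(r$p_value, 4),
        ifelse(r$unreliable, "yes", "no"))
    })
    lines <- c(lines, "",
               "## First vs last quarter (Pearson chi-square, 1 df)", "",
               .md_table(c("Indicator", "First", "Last", "First %", "Last %",
                           "Chi-square", "p", "Low expected counts"),
                         comp_rows))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Write feedback reports for every hospital
#'
#' Renders [render_feedback()] for each hospital in the KPI table and writes
#' `<hospital>.md` files plus a `comparisons.csv` to a directory.
#'
#' @inheritParams render_feedback
#' @param directory Output directory (created if absent).
#' @return Character vector of written file paths, invisibly.
#' @export
write_feedback_reports <- function(kpis, pooled, comparisons, directory,
                                   n_quarters = 4) {
  if (!dir.exists(directory)) {
    dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  }
  hospitals <- sort(unique(kpis$hospital_code[kpis$hospital_code != "(all)"]))
  paths <- vapply(hospitals, function(h) {
    p <- file.path(directory, paste0(h, ".md"))
    writeLines(render_feedback(kpis, pooled, comparisons, h, n_quarters), p,
               sep = "")
    p
  }, character(1))
  comp_path <- file.path(directory, "comparisons.csv")
  readr::write_csv(comparisons, comp_path, progress = FALSE)
  invisible(c(paths, comp_path))
}
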