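test_that("BrAC to BAC conversion doubles the reading and rejects negatives", {
  expect_identical(brac_to_bac(0.025), 0.05)
  expect_identical(brac_to_bac(0), 0)
  expect_identical(brac_to_bac(1.0), 2.0)
  expect_error(brac_to_bac(-0.1), class = "amirei_validation_error")
})

test_that("level of quantification is median + 10 IQR", {
  expect_equal(level_of_quantification(0.006, 0.004), 0.046)
  expect_identical(level_of_quantification(0, 0), 0)
  expect_equal(level_of_quantification(0.01, 0.002), 0.03)
  expect_error(level_of_quantification(-0.01, 0.002),
               class = "amirei_validation_error")
})

test_that("day aggregation computes omissions, MaxBAC and raw score", {
  d <- as.Date("2023-03-06")
  log <- dplyr::bind_rows(
    day_tests("A", d, c(8, 14, 20), TRUE, 0),
    day_tests("A", d + 1, c(8, 14, 20), c(TRUE, TRUE, FALSE), c(0, 0.03, 0))
  )
  days <- aggregate_days(log)
  expect_equal(days$n_omitted, c(0L, 1L))
  expect_equal(days$n_scheduled, c(3L, 3L))
  expect_equal(days$max_bac_permille, c(0, 0.06))
  expect_equal(days$treatment_day, c(0L, 1L))
  # day 2: one sober test (1), one positive (BrAC 0.03 -> BAC 0.06 >= 0.05,
  # so 0), and a first omission (5/6)
  expect_equal(days$raw_score, c(100, 100 * (1 + 0 + 5 / 6) / 3))
})

test_that("whole missing days expand to all-omitted under the schedule", {
  d <- as.Date("2023-03-06")
  log <- dplyr::bind_rows(
    day_tests("A", d, c(8, 14, 20), TRUE, 0),
    day_tests("A", d + 2, c(8, 14, 20), TRUE, 0)
  )
  days <- aggregate_days(log)
  expect_equal(nrow(days), 3L)
  gap_day <- days[days$date == d + 1, ]
  expect_equal(gap_day$n_scheduled, 3L)
  expect_equal(gap_day$n_omitted, 3L)
  expect_true(is.na(gap_day$max_bac_permille))
  # streaks k = 1, 2, 3 with K48 = 6: scores 5/6, 4/6, 3/6
  expect_equal(gap_day$raw_score, 100 * mean(c(5, 4, 3) / 6))
})

test_that("omission streaks span day boundaries and reset on performed tests", {
  d <- as.Date("2023-03-06")
  log <- dplyr::bind_rows(
    day_tests("A", d, c(8, 14, 20), c(TRUE, FALSE, FALSE), 0),
    day_tests("A", d + 1, c(8, 14, 20), c(FALSE, TRUE, FALSE), 0)
  )
  days <- aggregate_days(log)
  # day 1: 1, 5/6, 4/6; day 2: streak continues at k=3 (3/6), reset, then 5/6
  expect_equal(days$raw_score[1], 100 * mean(c(1, 5 / 6, 4 / 6)))
  expect_equal(days$raw_score[2], 100 * mean(c(3 / 6, 1, 5 / 6)))
})

test_that("MTBT is the longest performed-test gap intersecting each day", {
  d <- as.Date("2023-03-06")
  one_day <- day_tests("A", d, c(8, 20), TRUE, 0)
  m1 <- compute_mtbt(one_day)
  expect_equal(m1$mtbt_hours, 12)

  # performed 08:00 day 1, next 08:00 day 3: the 48-h gap covers all 3 days
  gap_log <- dplyr::bind_rows(
    day_tests("A", d, 8, TRUE, 0),
    day_tests("A", d + 2, 8, TRUE, 0)
  )
  m2 <- compute_mtbt(gap_log)
  expect_equal(m2$mtbt_hours[m2$date == d + 1], 48)

  # uniform 8-h spacing across midnight: every day reads 8 h
  uni <- dplyr::bind_rows(lapply(0:2, function(k) {
    day_tests("A", d + k, c(4, 12, 20), TRUE, 0)
  }))
  m3 <- compute_mtbt(uni)
  expect_equal(m3$mtbt_hours, rep(8, 3))
})

test_that("MTBT never decreases when an interior performed test is removed", {
  set.seed(11)
  d <- as.Date("2023-03-06")
  log <- dplyr::bind_rows(lapply(0:9, function(k) {
    day_tests("A", d + k, c(8, 14, 20), stats::runif(3) < 0.6, 0)
  }))
  perf_idx <- which(!is.na(log$performed_at))
  base <- compute_mtbt(log)
  for (i in perf_idx[-c(1, length(perf_idx))]) {
    thinned <- log
    thinned$performed_at[i] <- NA
    thinned$brac_permille[i] <- NA
    m <- compute_mtbt(thinned)
    defined <- !is.na(base$mtbt_hours)
    expect_true(all(m$mtbt_hours[defined] >= base$mtbt_hours[defined] - 1e-9))
  }
})

test_that("patients with zero performed tests get span MTBT with a warning", {
  d <- as.Date("2023-03-06")
  log <- dplyr::bind_rows(
    day_tests("A", d, c(8, 14, 20), FALSE),
    day_tests("A", d + 1, c(8, 14, 20), FALSE)
  )
  expect_warning(m <- compute_mtbt(log), "no performed tests")
  expect_true(all(m$mtbt_censored))
  expect_equal(m$mtbt_hours, rep(as.numeric(difftime(
    max(log$window_end), min(log$window_start), units = "hours"
  )), 2))
})

test_that("scheduled-count identity and MaxBAC identity hold on simulated data", {
  sim <- simulate_cohort(4, c(chaotic = 1), seed = 3, n_days = 40)
  days <- aggregate_days(sim$tests)
  # n_omitted + performed = n_scheduled
  perf <- sim$tests[!is.na(sim$tests$performed_at), ]
  perf$date <- as.Date(perf$window_start, tz = "UTC")
  counts <- dplyr::count(perf, patient_id, date)
  joined <- dplyr::left_join(days, counts, by = c("patient_id", "date"))
  joined$n[is.na(joined$n)] <- 0L
  expect_equal(joined$n_omitted + joined$n, joined$n_scheduled)
  # max_bac = 2 x max performed BrAC, exactly
  mx <- dplyr::summarise(dplyr::group_by(perf, patient_id, date),
                         mb = 2 * max(brac_permille), .groups = "drop")
  joined2 <- dplyr::inner_join(days, mx, by = c("patient_id", "date"))
  expect_identical(joined2$max_bac_permille, joined2$mb)
})

test_that("the day table round-trips through CSV", {
  sim <- simulate_cohort(2, c(controlled = 1), seed = 5, n_days = 25)
  days <- aggregate_days(sim$tests, truth_covariates(sim$truth))
  path <- withr::local_tempfile(fileext = ".csv")
  write_day_table(days, path)
  back <- read_day_table(path)
  expect_equal(as.data.frame(back), as.data.frame(days))
})

test_that("malformed test logs are rejected", {
  d <- as.Date("2023-03-06")
  ok <- day_tests("A", d, c(8, 14), TRUE, 0)
  unsorted <- ok[2:1, ]
  expect_error(validate_test_log(unsorted), "sorted",
               class = "amirei_validation_error")
  dup <- dplyr::bind_rows(ok, ok[1, ])
  expect_error(validate_test_log(dplyr::arrange(dup, window_start)),
               "duplicate", class = "amirei_validation_error")
  overlap <- ok
  overlap$window_end[1] <- overlap$window_start[2] + 1800
  expect_error(validate_test_log(overlap), "overlap",
               class = "amirei_validation_error")
  outside <- ok
  outside$performed_at[1] <- outside$window_end[1] + 3600
  expect_error(validate_test_log(outside), "within",
               class = "amirei_validation_error")
  ghost_brac <- ok
  ghost_brac$performed_at[1] <- NA
  expect_error(validate_test_log(ghost_brac), "performed",
               class = "amirei_validation_error")
})

test_that("test logs round-trip through the CSV reader", {
  sim <- simulate_cohort(2, c(weekend_binger = 1), seed = 9, n_days = 15)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(sim$tests, path, na = "")
  back <- read_test_log(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$tests))
})
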