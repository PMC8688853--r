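make_day_table <- function(n_patients, n_days, in_ee_fun,
                           start = as.Date("2023-01-02")) {
  tbl <- tidyr::expand_grid(
    patient_id = sprintf("P%02d", seq_len(n_patients)),
    treatment_day = seq_len(n_days) - 1L
  )
  tbl$date <- start + tbl$treatment_day
  days <- tibble::tibble(patient_id = tbl$patient_id, date = tbl$date,
                         treatment_day = tbl$treatment_day)
  out <- cohort_day_table(days, events = tibble::tibble(
    patient_id = character(), start_day = integer(), end_day = integer()
  ))
  out$in_ee <- in_ee_fun(out)
  out
}

test_that("the cohort day table carries event membership and calendar factors", {
  days <- tibble::tibble(
    patient_id = "A", date = as.Date("2023-01-02") + 0:6, treatment_day = 0:6
  )
  events <- tibble::tibble(patient_id = "A", start_day = 2L, end_day = 3L)
  tbl <- cohort_day_table(days, events)
  expect_equal(tbl$in_ee, c(0L, 0L, 1L, 1L, 0L, 0L, 0L))
  expect_equal(as.character(tbl$weekday),
               c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"))
  expect_equal(tbl$iso_week, rep(1L, 7))
  expect_equal(as.character(tbl$treatment_bin), rep("[0,30)", 7))
})

test_that("ISO week assignment follows ISO-8601, including 53-week years", {
  d <- as.Date(c("2020-12-31", "2021-01-04", "2016-01-01", "2015-12-28"))
  days <- tibble::tibble(patient_id = "A", date = d, treatment_day = 0:3)
  tbl <- cohort_day_table(days, events = tibble::tibble(
    patient_id = character(), start_day = integer(), end_day = integer()
  ))
  expect_equal(tbl$iso_week, c(53L, 1L, 53L, 53L))
})

test_that("grouped %EE uses the binomial Wald interval", {
  tbl <- make_day_table(4, 200, function(out) 0L)
  sat <- which(tbl$weekday == "Sat")
  tbl$in_ee[sat[1:40]] <- 1L
  # keep exactly 100 Saturday rows (40 in-EE) plus some reference rows
  tbl <- tbl[c(sat[1:100], which(tbl$weekday != "Sat")[1:50]), ]
  res <- percent_ee_by(tbl, "weekday")
  sat_row <- res[res$level == "Sat", ]
  expect_equal(sat_row$n_days, 100L)
  expect_equal(sat_row$percent_ee, 40)
  half_width <- 1.96 * sqrt(0.4 * 0.6 / 100) * 100
  expect_equal(sat_row$ci_high - sat_row$percent_ee, half_width, tolerance = 1e-3)
  expect_equal(sat_row$percent_ee - sat_row$ci_low, half_width, tolerance = 1e-3)

  none <- tbl
  none$in_ee <- 0L
  res0 <- percent_ee_by(none, "weekday")
  expect_true(all(res0$percent_ee == 0))
  expect_true(all(res0$ci_low == 0 & res0$ci_high == 0))

  expect_error(percent_ee_by(tbl[0, ], "weekday"),
               class = "amirei_validation_error")
})

test_that("grouped %EE recomposes exactly to the overall %EE", {
  set.seed(51)
  tbl <- make_day_table(6, 90, function(out) stats::rbinom(nrow(out), 1, 0.2))
  for (f in c("weekday", "iso_week", "treatment_bin")) {
    res <- percent_ee_by(tbl, f)
    recomposed <- sum(res$n_days * res$percent_ee) / sum(res$n_days)
    expect_equal(recomposed, 100 * mean(tbl$in_ee), tolerance = 1e-12)
  }
})

test_that("robust and naive standard errors agree without clustering", {
  # one day per patient: the cluster-robust (CR0) covariance of a saturated
  # one-factor logistic model equals the model-based covariance
  set.seed(52)
  n <- 600
  tbl <- tibble::tibble(
    patient_id = sprintf("P%04d", seq_len(n)),
    date = as.Date("2023-01-02") + seq_len(n),
    treatment_day = seq_len(n) - 1L,
    in_ee = stats::rbinom(n, 1, 0.3),
    weekday = factor(sample(c("Mon", "Tue", "Wed"), n, replace = TRUE),
                     levels = c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")),
    iso_week = 1L, treatment_bin = factor("[0,30)")
  )
  res <- cluster_logistic_test(tbl, "weekday", vcov_type = "CR0")
  fit <- stats::glm(in_ee ~ droplevels(weekday), family = stats::binomial(),
                    data = tbl)
  naive_se <- sqrt(diag(stats::vcov(fit)))[-1]
  robust_se <- (log(res$effects$ci_high) - log(res$effects$ci_low)) /
    (2 * stats::qnorm(0.975))
  expect_equal(unname(robust_se), unname(naive_se), tolerance = 1e-6)
})

test_that("the joint factor test detects an injected weekend effect", {
  set.seed(53)
  tbl <- make_day_table(20, 120, function(out) {
    p <- ifelse(out$weekday %in% c("Sat", "Sun"), 0.35, 0.1)
    stats::rbinom(nrow(out), 1, p)
  })
  res <- cluster_logistic_test(tbl, "weekday")
  expect_lt(res$p_value, 1e-4)
  sat_or <- res$effects$odds_ratio[res$effects$level == "Sat"]
  expect_gt(sat_or, 2)
})

test_that("degenerate factors are rejected and separated levels dropped", {
  tbl <- make_day_table(3, 21, function(out) stats::rbinom(nrow(out), 1, 0.3))
  one_level <- tbl
  one_level$weekday <- factor("Mon", levels = levels(tbl$weekday))
  expect_error(cluster_logistic_test(one_level, "weekday"),
               class = "amirei_validation_error")

  sep <- tbl
  sep$in_ee[sep$weekday == "Wed"] <- 0L
  expect_warning(res <- cluster_logistic_test(sep, "weekday"), "Wed")
  expect_false("Wed" %in% res$effects$level)
  expect_equal(res$dropped_levels, "Wed")
})
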