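# Test-log parsing, schedule semantics, and per-day aggregation.
#
# A "test log" is one row per scheduled breathalyzer test:
#   patient_id, window_start, window_end, performed_at (NA = omitted),
#   brac_permille (NA iff omitted).
# Timestamps are naive local clock times, stored as UTC POSIXct.

#' Convert breath alcohol content to a blood alcohol equivalent
#'
#' Breath alcohol content (BrAC, per mille) is converted to an approximate
#' blood alcohol content (BAC, per mille) by a fixed factor of 2.0, the
#' calibration used throughout the index computations.
#'
#' @param brac Numeric vector of breath alcohol content values (per mille),
#'   non-negative.
#' @return Numeric vector of blood alcohol equivalents (per mille).
#' @examples
#' brac_to_bac(0.025) # 0.05
#' @export
brac_to_bac <- function(brac) {
  if (!is.numeric(brac)) stop_validation("`brac` must be numeric")
  if (any(brac < 0, na.rm = TRUE)) stop_validation("`brac` must be non-negative")
  2.0 * brac
}

#' Level of quantification for sober breathalyzer readings
#'
#' The drinking threshold applied to BAC values is justified as a level of
#' quantification: median plus ten times the interquartile range of the
#' (drinking-insensitive) sober reading distribution. With cohort-scale sober
#' statistics (median 0.006 per mille, IQR 0.004 per mille) this gives
#' 0.046 per mille, supporting a 0.05 per mille threshold.
#'
#' @param median_bac Median of BAC readings (per mille), non-negative.
#' @param iqr_bac Interquartile range of BAC readings (per mille),
#'   non-negative.
#' @return The quantification threshold `median_bac + 10 * iqr_bac`.
#' @examples
#' level_of_quantification(0.006, 0.004) # 0.046
#' @export
level_of_quantification <- function(median_bac, iqr_bac) {
  if (any(median_bac < 0) || any(iqr_bac < 0)) {
    stop_validation("median and IQR must be non-negative")
  }
  median_bac + 10 * iqr_bac
}

test_log_cols <- c(
  "patient_id", "window_start", "window_end", "performed_at", "brac_permille"
)

#' Read a scheduled breathalyzer test log
#'
#' Reads and validates a test-log CSV with columns `patient_id`,
#' `window_start`, `window_end`, `performed_at` (empty = omitted) and
#' `brac_permille`. Timestamps must be ISO-8601; they are treated as naive
#' local times.
#'
#' @param path Path to a CSV file.
#' @return A tibble, one row per scheduled test, validated (see
#'   [validate_test_log()]).
#' @export
read_test_log <- function(path) {
  if (!file.exists(path)) stop_validation("test log not found: %s", path)
  tests <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      window_start = readr::col_datetime(),
      window_end = readr::col_datetime(),
      performed_at = readr::col_datetime(),
      brac_permille = readr::col_double()
    )
  )
  missing <- setdiff(test_log_cols, names(tests))
  if (length(missing) > 0) {
    stop_validation("test log %s lacks columns: %s", path, paste(missing, collapse = ", "))
  }
  validate_test_log(tests)
  tests
}

#' Read per-day covariates (drinks per drinking day, PEth)
#'
#' @param path CSV with columns `patient_id`, `date`, and optionally `ddd`
#'   (drinks per drinking day) and `peth_umol_l` (phosphatidyl ethanol,
#'   umol/L).
#' @return A tibble keyed by (`patient_id`, `date`).
#' @export
read_day_covariates <- function(path) {
  if (!file.exists(path)) stop_validation("covariate file not found: %s", path)
  cov <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      date = readr::col_date(),
      .default = readr::col_double()
    )
  )
  if (!all(c("patient_id", "date") %in% names(cov))) {
    stop_validation("covariate file must have patient_id and date columns")
  }
  if (any(cov$ddd < 0, na.rm = TRUE) || any(cov$peth_umol_l < 0, na.rm = TRUE)) {
    stop_validation("ddd and peth_umol_l must be non-negative")
  }
  cov
}

#' Validate a test log
#'
#' Checks the test-log contract: tests sorted by patient then window start,
#' non-overlapping and non-duplicated windows per patient, `performed_at`
#' inside its window, and `brac_permille` present exactly when the test was
#' performed.
#'
#' @param tests A test-log tibble (see [read_test_log()]).
#' @return `tests`, invisibly; raises a validation error otherwise.
#' @export
validate_test_log <- function(tests) {
  missing <- setdiff(test_log_cols, names(tests))
  if (length(missing) > 0) {
    stop_validation("test log lacks columns: %s", paste(missing, collapse = ", "))
  }
  if (any(is.na(tests$window_start)) || any(is.na(tests$window_end))) {
    stop_validation("window_start/window_end must not be missing")
  }
  if (any(tests$window_start >= tests$window_end)) {
    stop_validation("every window must satisfy window_start < window_end")
  }
  performed <- !is.na(tests$performed_at)
  if (any(performed != !is.na(tests$brac_permille))) {
    stop_validation("brac_permille must be present exactly for performed tests")
  }
  if (any(tests$brac_permille < 0, na.rm = TRUE)) {
    stop_validation("brac_permille must be non-negative")
  }
  inside <- tests$performed_at[performed] >= tests$window_start[performed] &
    tests$performed_at[performed] <= tests$window_end[performed]
  if (any(!inside)) {
    stop_validation("performed_at must lie within its scheduled window")
  }
  by_patient <- split(seq_len(nrow(tests)), tests$patient_id)
  for (idx in by_patient) {
    ws <- tests$window_start[idx]
    we <- tests$window_end[idx]
    if (is.unsorted(ws)) {
      stop_validation("tests must be sorted by patient then window_start")
    }
    if (anyDuplicated(ws) > 0) {
      stop_validation("duplicate (patient, window_start) in test log")
    }
    if (length(ws) > 1 && any(we[-length(we)] > ws[-1])) {
      stop_validation("scheduled windows of one patient overlap")
    }
  }
  invisible(tests)
}

# Canonical daytime positions for m tests/day, used when expanding missing
# whole days to all-omitted schedules (only counts and ordering matter
# downstream; performed-test gaps are unaffected).
schedule_hours <- function(m) {
  if (m == 1) 14 else seq(8, 20, length.out = m)
}

# Expand missing calendar days between a patient's first and last monitored
# day into all-omitted scheduled windows.
expand_schedule <- function(tests, tests_per_day = NULL) {
  tests$date <- as.Date(tests$window_start, tz = "UTC")
  fill_one <- function(df) {
    all_days <- seq(min(df$date), max(df$date), by = "day")
    missing_days <- setdiff(as.character(all_days), as.character(df$date))
    if (length(missing_days) == 0) return(df)
    m <- tests_per_day
    if (is.null(m)) {
      counts <- table(df$date)
      m <- as.integer(names(sort(table(counts), decreasing = TRUE))[1])
    }
    hrs <- schedule_hours(m)
    filler <- tibble::tibble(
      patient_id = df$patient_id[1],
      date = rep(as.Date(missing_days), each = m),
      window_start = as.POSIXct(rep(as.Date(missing_days), each = m), tz = "UTC") +
        rep((hrs - 0.5) * 3600, times = length(missing_days)),
      window_end = as.POSIXct(rep(as.Date(missing_days), each = m), tz = "UTC") +
        rep((hrs + 0.5) * 3600, times = length(missing_days)),
      performed_at = as.POSIXct(NA_real_, tz = "UTC"),
      brac_permille = NA_real_
    )
    dplyr::arrange(dplyr::bind_rows(df[names(filler)], filler), .data$window_start)
  }
  dplyr::bind_rows(lapply(split(tests, tests$patient_id), fill_one)) |>
    dplyr::select(dplyr::all_of(c(test_log_cols, "date")))
}

# Running count of consecutive omitted tests, spanning day boundaries and
# resetting on any performed test; the current test is included in the count.
omission_streak <- function(performed) {
  s <- seq_along(performed)
  last_perf <- cummax(ifelse(performed, s, 0L))
  as.integer(ifelse(performed, 0L, s - last_perf))
}

#' Aggregate scheduled tests into per-patient daily records
#'
#' Builds the per-day table that all index computations consume. Whole days
#' with no scheduled windows between a patient's first and last monitored day
#' are expanded to all-omitted days under the configured (or modal observed)
#' schedule, so the indices decay during device silence. Per day this
#' computes the scheduled and omitted test counts, `max_bac_permille`
#' (2.0 x the largest performed BrAC; absent if all tests were omitted), the
#' maximum time between tests (see [compute_mtbt()]), and the 0-100 raw
#' sobriety/compliance score `raw_score` (see [per_test_score()] and
#' [daily_raw_score()]).
#'
#' @param tests Validated test-log tibble.
#' @param covariates Optional per-day covariate tibble
#'   (see [read_day_covariates()]).
#' @param params An [ami_params()] object (BAC threshold, omission horizon,
#'   decay shape).
#' @param tests_per_day Scheduled tests per day used when expanding missing
#'   days; `NULL` infers each patient's modal daily count.
#' @return A tibble with one row per patient-day: `patient_id`, `date`,
#'   `treatment_day` (0-based), `n_scheduled`, `n_omitted`,
#'   `max_bac_permille`, `mtbt_hours`, `raw_score`, `ddd`, `peth_umol_l`.
#' @export
aggregate_days <- function(tests, covariates = NULL, params = ami_params(),
                           tests_per_day = NULL) {
  validate_test_log(tests)
  expanded <- expand_schedule(tests, tests_per_day)
  expanded <- expanded[order(expanded$patient_id, expanded$window_start), ]
  performed <- !is.na(expanded$performed_at)
  streak <- unlist(lapply(split(performed, expanded$patient_id), omission_streak),
                   use.names = FALSE)
  # ordered patient-day run index: rows are sorted, so days are contiguous
  n <- nrow(expanded)
  new_day <- c(TRUE, expanded$patient_id[-1] != expanded$patient_id[-n] |
                 expanded$date[-1] != expanded$date[-n])
  gi <- cumsum(new_day)
  n_sched <- tabulate(gi)
  score <- per_test_score(
    performed = performed,
    bac = brac_to_bac(expanded$brac_permille),
    streak = streak,
    tests_per_day = n_sched[gi],
    params = params
  )
  bac <- ifelse(performed, brac_to_bac(expanded$brac_permille), NA_real_)
  max_bac <- suppressWarnings(as.numeric(tapply(bac, gi, max, na.rm = TRUE)))
  max_bac[!is.finite(max_bac)] <- NA_real_
  first <- which(new_day)
  days <- tibble::tibble(
    patient_id = expanded$patient_id[first],
    date = expanded$date[first],
    n_scheduled = n_sched,
    n_omitted = as.integer(unname(rowsum(as.numeric(!performed), gi)[, 1])),
    max_bac_permille = unname(max_bac),
    # per-day mean of per-test scores on the 0-100 scale (daily_raw_score)
    raw_score = unname(100 * rowsum(score, gi)[, 1] / n_sched)
  )
  days <- days |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(treatment_day = as.integer(.data$date - min(.data$date))) |>
    dplyr::ungroup()
  mtbt <- compute_mtbt(tests)
  days <- dplyr::left_join(days, mtbt[c("patient_id", "date", "mtbt_hours")],
                           by = c("patient_id", "date"))
  if (!is.null(covariates)) {
    days <- dplyr::left_join(
      days,
      covariates[intersect(names(covariates), c("patient_id", "date", "ddd", "peth_umol_l"))],
      by = c("patient_id", "date")
    )
  }
  if (!"ddd" %in% names(days)) days$ddd <- NA_real_
  if (!"peth_umol_l" %in% names(days)) days$peth_umol_l <- NA_real_
  dplyr::select(
    days, "patient_id", "date", "treatment_day", "n_scheduled", "n_omitted",
    "max_bac_permille", "mtbt_hours", "raw_score", "ddd", "peth_umol_l"
  ) |>
    dplyr::arrange(.data$patient_id, .data$date)
}

#' Maximum time between tests (MTBT), attributed per day
#'
#' MTBT monitors test compliance: for each monitored day it is the longest
#' interval between consecutive performed tests among all such intervals that
#' intersect that calendar day. A day inside a multi-day omission gap carries
#' the full gap length, so MTBT exceeds 24 h during omission streaks (patient
#' means in the hundreds of hours are possible for poorly compliant
#' patients). Gaps to the monitoring-period boundaries are not counted; days
#' intersected by no performed-test gap have `NA`.
#'
#' @param tests Validated test-log tibble (performed and omitted rows).
#' @return Tibble `patient_id`, `date`, `mtbt_hours`, `mtbt_censored`
#'   (`TRUE` for patients with no performed tests at all, whose MTBT is
#'   reported as the full monitored span, with a warning).
#' @export
compute_mtbt <- function(tests) {
  validate_test_log(tests)
  tests$date <- as.Date(tests$window_start, tz = "UTC")
  one_patient <- function(df) {
    all_days <- seq(min(df$date), max(df$date), by = "day")
    mtbt <- rep(NA_real_, length(all_days))
    censored <- FALSE
    perf <- sort(df$performed_at[!is.na(df$performed_at)])
    if (length(perf) == 0) {
      warning(sprintf(
        "patient %s has no performed tests; MTBT reported as full monitored span",
        df$patient_id[1]
      ), call. = FALSE)
      mtbt[] <- as.numeric(difftime(max(df$window_end), min(df$window_start),
                                    units = "hours"))
      censored <- TRUE
    } else if (length(perf) >= 2) {
      gs <- perf[-length(perf)]
      ge <- perf[-1]
      len_h <- as.numeric(difftime(ge, gs, units = "hours"))
      d_start <- as.Date(gs, tz = "UTC")
      d_end <- as.Date(ge, tz = "UTC")
      # a gap ending exactly at midnight does not reach into the next day
      at_midnight <- as.numeric(ge) == as.numeric(as.POSIXct(d_end, tz = "UTC"))
      d_end[at_midnight] <- d_end[at_midnight] - 1
      n_cov <- as.integer(d_end - d_start) + 1L
      cov_date <- d_start[rep(seq_along(gs), n_cov)] + (sequence(n_cov) - 1L)
      cov_len <- len_h[rep(seq_along(gs), n_cov)]
      per_day <- tapply(cov_len, as.integer(cov_date), max)
      idx <- match(as.integer(names(per_day)), as.integer(all_days))
      mtbt[idx] <- as.numeric(per_day)
    }
    list(n = length(all_days), date = all_days, mtbt_hours = mtbt,
         mtbt_censored = censored)
  }
  parts <- lapply(split(tests, tests$patient_id), one_patient)
  tibble::tibble(
    patient_id = rep(names(parts), vapply(parts, `[[`, 0L, "n")),
    date = as.Date(unlist(lapply(parts, `[[`, "date")), origin = "1970-01-01"),
    mtbt_hours = unlist(lapply(parts, `[[`, "mtbt_hours"), use.names = FALSE),
    mtbt_censored = rep(vapply(parts, `[[`, TRUE, "mtbt_censored"),
                        vapply(parts, `[[`, 0L, "n"))
  )
}

#' Write / read the per-day table
#'
#' CSV round-trip helpers for the day table produced by [aggregate_days()].
#'
#' @param days Day tibble.
#' @param path Output path.
#' @return `write_day_table()` returns `path` invisibly; `read_day_table()`
#'   the tibble.
#' @export
write_day_table <- function(days, path) {
  readr::write_csv(days, path, na = "")
  invisible(path)
}

#' @rdname write_day_table
#' @export
read_day_table <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      date = readr::col_date(),
      treatment_day = readr::col_integer(),
      n_scheduled = readr::col_integer(),
      n_omitted = readr::col_integer(),
      .default = readr::col_double()
    )
  )
}
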