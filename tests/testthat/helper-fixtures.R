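# Builders for tiny in-code test logs.

ts_at <- function(date, hour) {
  as.POSIXct(as.Date(date), tz = "UTC") + hour * 3600
}

# One day's scheduled tests for one patient. `performed` is logical per
# window; performed tests default to the window centre.
day_tests <- function(patient_id, date, hours, performed, brac = 0) {
  n <- length(hours)
  performed <- rep_len(performed, n)
  brac <- rep_len(brac, n)
  centre <- ts_at(date, hours)
  tibble::tibble(
    patient_id = patient_id,
    window_start = centre - 1800,
    window_end = centre + 1800,
    performed_at = as.POSIXct(ifelse(performed, as.numeric(centre), NA_real_),
                              origin = "1970-01-01", tz = "UTC"),
    brac_permille = ifelse(performed, brac, NA_real_)
  )
}

# A fully compliant, all-sober patient: m tests/day for n days.
sober_log <- function(n_days, m = 3, patient_id = "S1",
                      start = as.Date("2023-01-02")) {
  dplyr::bind_rows(lapply(seq_len(n_days) - 1L, function(d) {
    day_tests(patient_id, start + d, schedule_hours_fixture(m), TRUE, 0)
  }))
}

schedule_hours_fixture <- function(m) seq(8, 20, length.out = m)

# Independent run-length oracle for event segmentation: flag days below the
# threshold, group consecutive flags.
brute_force_events <- function(rei, threshold) {
  flag <- which(rei < threshold)
  if (length(flag) == 0) {
    return(tibble::tibble(start_day = integer(), end_day = integer(),
                          length = integer(), dist_previous = integer()))
  }
  grp <- cumsum(c(1L, as.integer(diff(flag) != 1L)))
  starts <- as.integer(tapply(flag, grp, min)) - 1L
  ends <- as.integer(tapply(flag, grp, max)) - 1L
  tibble::tibble(
    start_day = starts, end_day = ends, length = ends - starts + 1L,
    dist_previous = c(NA_integer_, starts[-1] - ends[-length(ends)])
  )
}

# Closed-form (weighted-sum) exponential smoothing, independent of the
# recursive implementation.
closed_form_smooth <- function(x, alpha) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    t <- i - 1L
    if (t == 0) return(x[1])
    k <- 0:(t - 1)
    (1 - alpha)^t * x[1] + sum(alpha * (1 - alpha)^k * x[i - k])
  }, numeric(1))
}
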