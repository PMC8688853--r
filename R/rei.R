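# The Recovery and Exacerbation Index (REI) and exacerbation-event (EE)
# segmentation with per-patient summaries.

#' Recovery and Exacerbation Index from two AMI series
#'
#' The REI is the ratio of a short-memory AMI (numerator, default alpha 0.45)
#' to a long-memory AMI (denominator, default alpha 0.06). Values below 1
#' mean the patient is faring worse from a short-term than from a long-term
#' perspective, independent of the absolute index level. Because smoothing
#' weights are positive, the denominator can only be 0 when the numerator is
#' too (an all-zero history); that 0/0 case is defined as 1. Values are
#' capped (default 10) because the ratio climbs far above 1 after a deep
#' dive followed by rapid recovery; the cap never affects event detection,
#' which only uses the region below the threshold.
#'
#' @param ami_short,ami_long Aligned numeric AMI series for one patient.
#' @param cap Upper cap for the ratio (default 10).
#' @return Numeric REI series.
#' @examples
#' compute_rei(55, 100) # 0.55, a clear downward trend
#' @export
compute_rei <- function(ami_short, ami_long, cap = 10) {
  if (length(ami_short) != length(ami_long)) {
    stop_validation("AMI series must be aligned (equal length)")
  }
  if (any(is.na(ami_short)) || any(is.na(ami_long))) {
    stop_validation("AMI series must not contain NA")
  }
  if (any(ami_long == 0 & ami_short != 0)) {
    stop_validation("denominator AMI is 0 where numerator is not; series are inconsistent")
  }
  rei <- ifelse(ami_long == 0, 1, ami_short / ami_long)
  pmin(rei, cap)
}

#' Add an REI column to an AMI family table
#'
#' @param ami AMI table from [compute_ami_family()].
#' @param pair Numerator/denominator index names, default `c(45, 6)`
#'   (the pair giving the best contrast between baseline and exacerbation).
#' @param cap See [compute_rei()].
#' @return Tibble `patient_id`, `date`, `treatment_day`, `rei`.
#' @export
add_rei <- function(ami, pair = c(45, 6), cap = 10) {
  cols <- paste0("ami_", pair)
  if (!all(cols %in% names(ami))) {
    stop_validation("AMI table lacks columns %s", paste(setdiff(cols, names(ami)), collapse = ", "))
  }
  out <- ami[c("patient_id", "date", "treatment_day")]
  out$rei <- compute_rei(ami[[cols[1]]], ami[[cols[2]]], cap = cap)
  out
}

#' Segment an REI series into exacerbation events
#'
#' An exacerbation event (EE) is a maximal run of consecutive days with REI
#' strictly below the threshold (default 0.8; a day exactly at the threshold
#' is not in an event). Each event records its 0-based start/end treatment
#' days (inclusive), its length in days, and the distance in days from the
#' end of the previous event to its own start (`NA` for the first event).
#'
#' @param rei Numeric REI series for one patient (day t at index t+1).
#' @param threshold Positive REI threshold, default 0.8.
#' @return Tibble `start_day`, `end_day`, `length`, `dist_previous`.
#' @examples
#' detect_events(c(1, 1, 0.7, 0.7, 0.9, 0.6, 1))
#' @export
detect_events <- function(rei, threshold = 0.8) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop_validation("threshold must be a single positive number")
  }
  if (length(rei) == 0 || any(is.na(rei))) {
    stop_validation("rei must be a non-empty numeric series without NA")
  }
  below <- rei < threshold
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  ev <- tibble::tibble(
    start_day = starts[keep] - 1L,
    end_day = ends[keep] - 1L
  )
  ev$length <- ev$end_day - ev$start_day + 1L
  ev$dist_previous <- ev$start_day - dplyr::lag(ev$end_day)
  ev
}

#' Segment every patient's REI series
#'
#' @param rei_tbl REI table from [add_rei()].
#' @param threshold See [detect_events()].
#' @param min_event_length Drop events shorter than this many days
#'   (default 1 keeps all; 2 keeps only multi-day events, the display rule
#'   used when single-day dips are considered noise).
#' @return Tibble `patient_id`, `start_day`, `end_day`, `start_date`,
#'   `end_date`, `length_days`, `dist_previous_days`. Distances are computed
#'   before length filtering so they always refer to the previous detected
#'   event.
#' @export
detect_cohort_events <- function(rei_tbl, threshold = 0.8, min_event_length = 1) {
  one <- function(df) {
    df <- dplyr::arrange(df, .data$treatment_day)
    ev <- detect_events(df$rei, threshold)
    tibble::tibble(
      start_day = ev$start_day,
      end_day = ev$end_day,
      start_date = df$date[ev$start_day + 1L],
      end_date = df$date[ev$end_day + 1L],
      length_days = ev$length,
      dist_previous_days = ev$dist_previous
    )
  }
  out <- rei_tbl |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
  out[out$length_days >= min_event_length, ]
}

#' Summarize one patient's monitored course
#'
#' Compiles the per-patient overview of the drinking pattern: monitored days,
#' the percentage of days inside exacerbation events (%EE), event count,
#' mean and maximum event length, mean distance since the previous event
#' (undefined for the first event, which is excluded from the mean), plus
#' means of AMI-21, MTBT, DDD and PEth where available.
#'
#' @param days One patient's day table.
#' @param ami That patient's AMI table (used for the `ami_21` mean when the
#'   column is present).
#' @param events That patient's events (from [detect_cohort_events()]).
#' @param min_event_length Only events at least this long enter the summary.
#' @return One-row tibble `patient_id`, `treatment_days`, `percent_ee`,
#'   `ee_count`, `mean_ee_length`, `max_ee_length`, `mean_dist_previous`,
#'   `ami21_mean`, `mtbt_mean`, `ddd_mean`, `peth_mean`.
#' @export
summarize_patient <- function(days, ami = NULL, events, min_event_length = 1) {
  n_days <- nrow(days)
  if (n_days == 0) stop_validation("patient has zero monitored days")
  ev <- events[events$length_days >= min_event_length, ]
  in_ee_days <- sum(ev$length_days)
  if (in_ee_days > n_days) stop_validation("events cover more days than are monitored")
  tibble::tibble(
    patient_id = days$patient_id[1],
    treatment_days = n_days,
    percent_ee = 100 * in_ee_days / n_days,
    ee_count = nrow(ev),
    mean_ee_length = if (nrow(ev) > 0) mean(ev$length_days) else NA_real_,
    max_ee_length = if (nrow(ev) > 0) max(ev$length_days) else NA_integer_,
    mean_dist_previous = if (any(!is.na(ev$dist_previous_days))) {
      mean(ev$dist_previous_days, na.rm = TRUE)
    } else NA_real_,
    ami21_mean = if (!is.null(ami) && "ami_21" %in% names(ami)) {
      mean(ami$ami_21)
    } else NA_real_,
    mtbt_mean = mean(days$mtbt_hours, na.rm = TRUE),
    ddd_mean = if (any(!is.na(days$ddd))) mean(days$ddd, na.rm = TRUE) else NA_real_,
    peth_mean = if (any(!is.na(days$peth_umol_l))) {
      mean(days$peth_umol_l, na.rm = TRUE)
    } else NA_real_
  )
}

#' Summarize every patient in a cohort
#'
#' @param days Cohort day table.
#' @param ami Cohort AMI table.
#' @param events Cohort events.
#' @inheritParams summarize_patient
#' @return One row per patient (see [summarize_patient()]).
#' @export
summarize_cohort <- function(days, ami = NULL, events, min_event_length = 1) {
  ids <- unique(days$patient_id)
  out <- lapply(ids, function(id) {
    summarize_patient(
      days[days$patient_id == id, ],
      if (!is.null(ami)) ami[ami$patient_id == id, ],
      events[events$patient_id == id, ],
      min_event_length = min_event_length
    )
  })
  dplyr::bind_rows(out)
}
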