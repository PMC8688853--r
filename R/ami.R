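# The Addiction Monitoring Index (AMI): per-test scoring with
# consecutive-omission imputation, daily raw score, and exponential smoothing.

#' Parameters of the AMI computation
#'
#' @param alpha Smoothing factor in (0, 1]; the relative weight of the
#'   present day versus history. AMI-N uses `alpha = N/100` (AMI-21 is the
#'   original therapist-facing index).
#' @param bac_threshold Blood-alcohol threshold (per mille) above which a
#'   performed test counts as drinking. Default 0.05, the level-of-
#'   quantification-backed threshold (see [level_of_quantification()]).
#' @param scale_max Top of the index scale (fixed at 100).
#' @param omission_horizon_hours Length of the omission streak, in hours,
#'   after which an omitted test carries the same (zero) weight as a positive
#'   test. Default 48.
#' @param decay_exponent Shape of the imputation decay over the streak:
#'   the score of the k-th consecutive omission is
#'   `max(0, 1 - (k/K)^decay_exponent)` where `K` is the number of scheduled
#'   tests in the horizon. 1 (default) is linear; values != 1 bend the decay
#'   while preserving the horizon endpoint.
#' @return An object of class `ami_params`.
#' @export
ami_params <- function(alpha = 0.21, bac_threshold = 0.05, scale_max = 100,
                       omission_horizon_hours = 48, decay_exponent = 1) {
  if (alpha <= 0 || alpha > 1) stop_validation("alpha must be in (0, 1]")
  if (bac_threshold <= 0) stop_validation("bac_threshold must be positive")
  if (omission_horizon_hours <= 0) stop_validation("omission_horizon_hours must be positive")
  if (decay_exponent <= 0) stop_validation("decay_exponent must be positive")
  if (!identical(as.numeric(scale_max), 100)) {
    stop_validation("scale_max is fixed at 100")
  }
  structure(
    list(alpha = alpha, bac_threshold = bac_threshold, scale_max = 100,
         omission_horizon_hours = omission_horizon_hours,
         decay_exponent = decay_exponent),
    class = "ami_params"
  )
}

#' @export
print.ami_params <- function(x, ...) {
  cat(sprintf(
    "AMI parameters: alpha %.2f, BAC threshold %.3f permille, omission horizon %g h, decay exponent %g\n",
    x$alpha, x$bac_threshold, x$omission_horizon_hours, x$decay_exponent
  ))
  invisible(x)
}

#' Score one scheduled test on the 0-1 sobriety/compliance scale
#'
#' A performed test scores 1 if its BAC equivalent is below the threshold and
#' 0 if at or above it. An omitted test receives an imputed score that is
#' lowered for each consecutive omitted test: with streak length `k` (the
#' current omission included, streaks spanning day boundaries and resetting
#' on any performed test) the score is `max(0, 1 - (k/K)^g)` where
#' `K = tests_per_day * omission_horizon_hours / 24` and `g` is the decay
#' exponent. Once the streak spans the 48-h horizon an omission therefore
#' carries the same zero score as a positive test; before that, a positive
#' test is weighted more negatively than a missed one.
#'
#' @param performed Logical vector: was the test performed?
#' @param bac BAC equivalent (per mille) for performed tests, `NA` otherwise.
#' @param streak Consecutive-omission count including the current test; must
#'   be 0 for performed tests.
#' @param tests_per_day Scheduled tests per day (2-5 in routine monitoring),
#'   recycled against the other arguments.
#' @param params [ami_params()].
#' @return Numeric vector of scores in \[0, 1\].
#' @examples
#' per_test_score(TRUE, bac = 0.03, tests_per_day = 3)  # 1: below threshold
#' per_test_score(FALSE, streak = 6, tests_per_day = 3) # 0: 48 h of omission
#' @export
per_test_score <- function(performed, bac = NA_real_, streak = 0L,
                           tests_per_day = 3L, params = ami_params()) {
  n <- max(length(performed), length(bac), length(streak), length(tests_per_day))
  performed <- rep_len(as.logical(performed), n)
  bac <- rep_len(as.numeric(bac), n)
  streak <- rep_len(as.numeric(streak), n)
  tests_per_day <- rep_len(as.numeric(tests_per_day), n)
  if (any(streak < 0)) stop_validation("streak must be non-negative")
  if (any(performed & streak > 0)) {
    stop_validation("a performed test cannot carry a positive omission streak")
  }
  if (any(!performed & streak < 1)) {
    stop_validation("an omitted test must have streak >= 1")
  }
  if (any(performed & is.na(bac))) {
    stop_validation("performed tests require a BAC value")
  }
  k_horizon <- tests_per_day * params$omission_horizon_hours / 24
  score <- numeric(n)
  score[performed] <- as.numeric(bac[performed] < params$bac_threshold)
  om <- !performed
  score[om] <- pmax(0, 1 - (streak[om] / k_horizon[om])^params$decay_exponent)
  score
}

#' Daily raw score
#'
#' The day's raw value `x_t` on the 0-100 index scale: 100 times the
#' arithmetic mean of the day's per-test scores. The mean keeps days with
#' different scheduled counts comparable.
#'
#' @param scores Numeric vector of per-test scores in \[0, 1\]; at least one.
#' @return `x_t` in \[0, 100\].
#' @export
daily_raw_score <- function(scores) {
  if (length(scores) == 0) stop_validation("a day must have at least one scheduled test")
  if (any(is.na(scores)) || any(scores < 0 | scores > 1)) {
    stop_validation("per-test scores must lie in [0, 1]")
  }
  100 * mean(scores)
}

#' Exponential smoothing of a daily series
#'
#' The smoothing recurrence at the core of the index family:
#' `s_0 = x_0`; `s_t = alpha * x_t + (1 - alpha) * s_{t-1}` for `t > 0`.
#' Small alpha smooths out short-term events (long-term perspective); large
#' alpha highlights them.
#'
#' @param x Non-empty numeric series (daily raw scores).
#' @param alpha Smoothing factor in (0, 1].
#' @return Numeric vector `s` of the same length.
#' @examples
#' exp_smooth(c(100, 100, 0), 0.45) # 100 100 55
#' @export
exp_smooth <- function(x, alpha) {
  if (length(x) == 0) stop_validation("series must be non-empty")
  if (any(is.na(x))) stop_validation("series must not contain NA")
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1) {
    stop_validation("alpha must be a single value in (0, 1]")
  }
  if (length(x) == 1L) return(as.numeric(x))
  s_rest <- stats::filter(alpha * x[-1L], 1 - alpha, method = "recursive",
                          init = x[1L])
  c(x[1L], as.numeric(s_rest))
}

#' Compute a family of AMI series
#'
#' Smooths each patient's daily raw score with several smoothing factors at
#' once. `AMI-N` denotes `alpha = N/100`; the family 6, 12, 21, 45 spans very
#' long-term to very short-term perspectives (AMI-45/AMI-6 is the default
#' trend-ratio pair, AMI-21 the original monitoring index).
#'
#' @param days Day table from [aggregate_days()]; each patient's days must be
#'   contiguous (treatment_day 0, 1, 2, ...).
#' @param family Integer vector of index names N (alpha = N/100). Default
#'   `c(6, 12, 21, 45)`.
#' @return Tibble `patient_id`, `date`, `treatment_day`, plus one `ami_<N>`
#'   column per family member, values on the 0-100 scale.
#' @export
compute_ami_family <- function(days, family = c(6, 12, 21, 45)) {
  if (length(family) == 0 || any(family <= 0 | family > 100)) {
    stop_validation("family members must be in 1..100 (alpha = N/100)")
  }
  check_contiguous(days)
  smooth_one <- function(df) {
    out <- df[c("patient_id", "date", "treatment_day")]
    for (N in family) {
      out[[paste0("ami_", N)]] <- exp_smooth(df$raw_score, N / 100)
    }
    out
  }
  days <- dplyr::arrange(days, .data$patient_id, .data$treatment_day)
  dplyr::bind_rows(lapply(split(days, days$patient_id), smooth_one)) |>
    dplyr::select("patient_id", "date", "treatment_day", dplyr::starts_with("ami_"))
}

# days must be one row per consecutive treatment day per patient
check_contiguous <- function(days) {
  ok <- days |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      contiguous = all(sort(.data$treatment_day) == seq_len(dplyr::n()) - 1L) &&
        !anyDuplicated(.data$date),
      .groups = "drop"
    )
  if (!all(ok$contiguous)) {
    stop_validation(
      "days must be contiguous per patient (treatment_day 0..n-1, no duplicate dates): %s",
      paste(ok$patient_id[!ok$contiguous], collapse = ", ")
    )
  }
  invisible(days)
}
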