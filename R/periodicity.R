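# Cohort-level periodicity of exacerbation events: %EE by weekday, ISO week
# and treatment-time bin, with cluster-robust logistic tests.

#' Build the cohort day table with event membership and calendar factors
#'
#' One row per patient-day with the binary in-event indicator and the three
#' grouping factors used in periodicity analysis: weekday (Mon-Sun), ISO-8601
#' week number, and treatment-day bin (half-open 30-day bins by default,
#' covering \[0, 390) in 13 bins).
#'
#' @param days Cohort day table from [aggregate_days()].
#' @param events Cohort events from [detect_cohort_events()].
#' @param bin_width Width of treatment-day bins in days (default 30).
#' @return Tibble `patient_id`, `date`, `treatment_day`, `in_ee`, `weekday`,
#'   `iso_week`, `treatment_bin`.
#' @export
cohort_day_table <- function(days, events, bin_width = 30) {
  if (bin_width <= 0) stop_validation("bin_width must be positive")
  tbl <- days[c("patient_id", "date", "treatment_day")]
  tbl$in_ee <- 0L
  if (nrow(events) > 0) {
    covered <- events |>
      dplyr::mutate(day = purrr_map2_seq(.data$start_day, .data$end_day)) |>
      tidyr::unnest("day")
    key <- paste(tbl$patient_id, tbl$treatment_day)
    tbl$in_ee[key %in% paste(covered$patient_id, covered$day)] <- 1L
  }
  tbl$weekday <- weekday_of(tbl$date)
  tbl$iso_week <- iso_week_of(tbl$date)
  bin_idx <- tbl$treatment_day %/% bin_width
  lab <- sprintf("[%d,%d)", sort(unique(bin_idx)) * bin_width,
                 (sort(unique(bin_idx)) + 1) * bin_width)
  tbl$treatment_bin <- factor(sprintf("[%d,%d)", bin_idx * bin_width,
                                      (bin_idx + 1) * bin_width), levels = lab)
  tbl
}

# tiny local stand-in to avoid importing purrr for one map
purrr_map2_seq <- function(a, b) mapply(seq, a, b, SIMPLIFY = FALSE)

#' Percentage of days in exacerbation by a calendar factor
#'
#' Groups the cohort day table by one factor and reports the percentage of
#' days in an exacerbation event with a day-level 95% Wald interval. The
#' interval is a visualization aid; inference that respects the repeated
#' measures per patient comes from [cluster_logistic_test()].
#'
#' @param table Cohort day table from [cohort_day_table()].
#' @param factor One of `"weekday"`, `"iso_week"`, `"treatment_bin"`.
#' @param conf Confidence level, default 0.95.
#' @return Tibble `level`, `n_days`, `n_patients`, `percent_ee`, `ci_low`,
#'   `ci_high`.
#' @export
percent_ee_by <- function(table, factor = c("weekday", "iso_week", "treatment_bin"),
                          conf = 0.95) {
  if (nrow(table) == 0) stop_validation("cohort day table is empty")
  factor <- match.arg(factor)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  table |>
    dplyr::group_by(level = .data[[factor]]) |>
    dplyr::summarise(
      n_days = dplyr::n(),
      n_patients = dplyr::n_distinct(.data$patient_id),
      percent_ee = 100 * mean(.data$in_ee),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      se = 100 * sqrt((.data$percent_ee / 100) * (1 - .data$percent_ee / 100) / .data$n_days),
      ci_low = .data$percent_ee - z * .data$se,
      ci_high = .data$percent_ee + z * .data$se
    ) |>
    dplyr::select(-"se")
}

#' Cluster-robust logistic test of a periodicity factor
#'
#' Fits the day-level logistic model `in_ee ~ factor` and tests the factor
#' jointly with a Wald test under a patient-clustered sandwich covariance,
#' accounting for repeated measures per patient. The default covariance
#' carries the standard G/(G-1) small-cluster adjustment and the joint
#' statistic is referred to an F distribution with (q, G-1) degrees of
#' freedom (G clusters, q tested coefficients); `vcov_type = "CR0"` gives
#' the unadjusted sandwich. Levels with no outcome variation (all days in or
#' all days out of events) cannot enter the fit; their rows are dropped from
#' the joint test with a warning.
#'
#' @param table Cohort day table from [cohort_day_table()].
#' @param factor One of `"weekday"`, `"iso_week"`, `"treatment_bin"`.
#' @param vcov_type `"CR1"` (default) or `"CR0"`.
#' @return List with `statistic` (F), `df1`, `df2`, `p_value`, `n_clusters`,
#'   `method`, `dropped_levels`, and `effects`: a tibble of per-level odds
#'   ratios vs. the reference level with robust 95% intervals.
#' @export
cluster_logistic_test <- function(table, factor = c("weekday", "iso_week", "treatment_bin"),
                                  vcov_type = c("CR1", "CR0")) {
  factor <- match.arg(factor)
  vcov_type <- match.arg(vcov_type)
  f <- droplevels(base::factor(table[[factor]]))
  if (nlevels(f) < 2) stop_validation("factor must have at least 2 levels")
  prop <- tapply(table$in_ee, f, mean)
  separated <- names(prop)[prop %in% c(0, 1)]
  if (length(separated) > 0) {
    warning(sprintf(
      "levels with no outcome variation dropped from the joint test: %s",
      paste(separated, collapse = ", ")
    ), call. = FALSE)
    keep <- !(as.character(f) %in% separated)
    table <- table[keep, ]
    f <- droplevels(f[keep])
    if (nlevels(f) < 2) {
      stop_validation("fewer than 2 usable levels after dropping separated levels")
    }
  }
  d <- data.frame(in_ee = table$in_ee, f = f, patient_id = table$patient_id)
  fit <- stats::glm(in_ee ~ f, family = stats::binomial(), data = d)
  V <- sandwich::vcovCL(fit, cluster = d$patient_id, type = "HC0",
                        cadjust = (vcov_type == "CR1"))
  idx <- grep("^f", names(stats::coef(fit)))
  b <- stats::coef(fit)[idx]
  G <- length(unique(d$patient_id))
  # the sandwich meat has rank at most G; invert on the positive eigenspace
  # so few-cluster designs degrade to a reduced-rank Wald test
  Vb <- V[idx, idx, drop = FALSE]
  ev <- eigen(Vb, symmetric = TRUE)
  pos <- ev$values > max(ev$values) * 1e-10
  q <- sum(pos)
  U <- ev$vectors[, pos, drop = FALSE]
  Vinv <- U %*% diag(1 / ev$values[pos], nrow = q) %*% t(U)
  W <- as.numeric(t(b) %*% Vinv %*% b)
  Fstat <- W / q
  p <- stats::pf(Fstat, q, G - 1, lower.tail = FALSE)
  # with few clusters the sandwich is rank-deficient; clip tiny negative
  # diagonal entries before taking standard errors
  se <- sqrt(pmax(diag(V)[idx], 0))
  z <- stats::qnorm(0.975)
  effects <- tibble::tibble(
    level = levels(f)[-1],
    log_odds_ratio = unname(b),
    odds_ratio = exp(unname(b)),
    ci_low = exp(unname(b) - z * se),
    ci_high = exp(unname(b) + z * se)
  )
  list(
    statistic = Fstat, df1 = q, df2 = G - 1, p_value = p, n_clusters = G,
    method = sprintf("cluster-robust Wald F (%s sandwich, patient clusters)", vcov_type),
    dropped_levels = separated, effects = effects
  )
}
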