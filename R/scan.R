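# ANOVA-based selection of the REI threshold: for each candidate threshold,
# label drinks-per-drinking-day (DDD) observations by event membership and
# compare the two bins by their F-ratio.

#' Scan REI thresholds with a DDD ANOVA
#'
#' For each candidate threshold tau on a grid (default 17 equally spaced
#' values over \[0.05, 1.1\]), days carrying a DDD observation are divided
#' into two bins by `rei < tau`. The mean DDD difference between bins is
#' summarized by the ANOVA F-ratio of a one-way model (`ddd ~ bin`) and of a
#' two-way model adding patient as a fixed factor (`ddd ~ patient + bin`,
#' F for the bin term). A threshold for which one bin is empty yields `NA`
#' F-ratios rather than an error.
#'
#' @param rei_tbl REI table from [add_rei()].
#' @param day_covariates Tibble with `patient_id`, `date`, `ddd`; days
#'   without DDD are excluded.
#' @param grid Numeric vector of candidate thresholds.
#' @param include_zero_ddd Keep days reported as DDD = 0 (sober days)?
#'   Default `TRUE`.
#' @return A tibble of class `rei_scan`: `threshold`, `f_plain`,
#'   `f_patient_factor`, `n_bin0`, `n_bin1`.
#' @export
scan_thresholds <- function(rei_tbl, day_covariates,
                            grid = seq(0.05, 1.1, length.out = 17),
                            include_zero_ddd = TRUE) {
  if (length(grid) == 0 || any(grid <= 0)) {
    stop_validation("grid thresholds must be positive")
  }
  if (!all(c("patient_id", "date", "ddd") %in% names(day_covariates))) {
    stop_validation("day_covariates needs patient_id, date, ddd")
  }
  obs <- dplyr::inner_join(
    rei_tbl[c("patient_id", "date", "rei")],
    day_covariates[c("patient_id", "date", "ddd")],
    by = c("patient_id", "date")
  )
  obs <- obs[!is.na(obs$ddd), ]
  if (!include_zero_ddd) obs <- obs[obs$ddd > 0, ]
  if (nrow(obs) == 0) stop_validation("no DDD observations joinable to REI days")
  multi_patient <- length(unique(obs$patient_id)) > 1
  one_tau <- function(tau) {
    bin <- obs$rei < tau
    n1 <- sum(bin)
    n0 <- sum(!bin)
    if (n0 == 0 || n1 == 0) {
      return(tibble::tibble(threshold = tau, f_plain = NA_real_,
                            f_patient_factor = NA_real_, n_bin0 = n0, n_bin1 = n1))
    }
    d <- data.frame(ddd = obs$ddd, bin = factor(bin, levels = c(FALSE, TRUE)),
                    patient = factor(obs$patient_id))
    f_plain <- stats::anova(stats::lm(ddd ~ bin, data = d))["bin", "F value"]
    f_pat <- if (multi_patient) {
      # sequential ANOVA with bin last = added-last F for the bin term
      stats::anova(stats::lm(ddd ~ patient + bin, data = d))["bin", "F value"]
    } else {
      f_plain
    }
    tibble::tibble(threshold = tau, f_plain = f_plain, f_patient_factor = f_pat,
                   n_bin0 = n0, n_bin1 = n1)
  }
  out <- dplyr::bind_rows(lapply(sort(grid), one_tau))
  class(out) <- c("rei_scan", class(out))
  out
}

#' Pick the recommended threshold from a scan
#'
#' Returns the threshold maximizing the F-ratio (the patient-adjusted model
#' is preferred when available; ties break toward the lower threshold),
#' together with the qualitative high-F plateau: the range of thresholds
#' whose F reaches at least 80% of the maximum. On drinking-driven data the
#' F-curve is low at both grid extremes and high in an interior range.
#'
#' @param scan An `rei_scan` from [scan_thresholds()].
#' @param prefer `"f_patient_factor"` (default) or `"f_plain"`.
#' @return List with `threshold`, `f`, `model`, and `plateau` (length-2
#'   numeric range).
#' @export
select_threshold <- function(scan, prefer = c("f_patient_factor", "f_plain")) {
  prefer <- match.arg(prefer)
  f <- scan[[prefer]]
  if (all(is.na(f))) stop_validation("all F-ratios are absent; cannot select a threshold")
  if (sum(!is.na(f)) < 3) stop_validation("need at least 3 thresholds with defined F-ratios")
  best <- which(f == max(f, na.rm = TRUE))[1]
  high <- which(!is.na(f) & f >= 0.8 * f[best])
  list(
    threshold = scan$threshold[best],
    f = f[best],
    model = prefer,
    plateau = range(scan$threshold[high])
  )
}
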