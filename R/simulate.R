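# Synthetic breathalyzer cohorts with known ground truth.
#
# The generator emulates the observable structure the indices operate on:
# 2-5 scheduled tests/day, episodic drinking with weekday/holiday-week/
# treatment-time effects and multi-day persistence, BrAC magnitudes around
# the 0.05 per mille BAC threshold, and omission behavior that worsens on
# drinking days (so events can be triggered by poor compliance alone).

ARCHETYPES <- c("abstinent", "controlled", "weekend_binger", "periodic_heavy", "chaotic")

default_ramp <- function() {
  # mild treatment-time profile: risk climbs over the first ~3 months,
  # then eases below baseline
  data.frame(day = c(0, 105, 390), logit = c(0, 0.5, -0.3))
}

archetype_presets <- function() {
  wd0 <- stats::setNames(rep(0, 7), WEEKDAY_LEVELS)
  wk0 <- rep(0, 53)
  holiday <- wk0
  holiday[c(1, 51, 52, 53)] <- 1.0   # Christmas / New Year weeks
  holiday[c(25, 26)] <- 0.8          # midsummer
  weekend <- wd0
  weekend[c("Sat", "Sun")] <- 2.5
  weekend["Fri"] <- 1.0
  list(
    abstinent = list(
      base_logit = -12, weekday_logits = wd0, week_logits = wk0,
      ramp = data.frame(day = c(0, 390), logit = c(0, 0)),
      episode_persistence = 0, episode_sd = 0.5,
      ddd_mu = log(3), ddd_sigma = 0.4,
      omission_base = 0.05, omission_drinking = 0.05
    ),
    controlled = list(
      base_logit = -2.2, weekday_logits = wd0 + c(0, 0, 0, 0, 0.4, 0.4, 0),
      week_logits = wk0, ramp = default_ramp(),
      episode_persistence = 0.3, episode_sd = 1.0,
      ddd_mu = log(1.5), ddd_sigma = 0.3,
      omission_base = 0.08, omission_drinking = 0.35
    ),
    weekend_binger = list(
      base_logit = -3, weekday_logits = weekend, week_logits = holiday,
      ramp = default_ramp(),
      episode_persistence = 0.2, episode_sd = 0.8,
      ddd_mu = log(6), ddd_sigma = 0.4,
      omission_base = 0.08, omission_drinking = 0.5
    ),
    periodic_heavy = list(
      base_logit = -2.5, weekday_logits = wd0, week_logits = wk0,
      ramp = default_ramp(),
      episode_persistence = 0.93, episode_sd = 2.2,
      ddd_mu = log(8), ddd_sigma = 0.4,
      omission_base = 0.1, omission_drinking = 0.65
    ),
    chaotic = list(
      base_logit = -1.0, weekday_logits = wd0, week_logits = holiday,
      ramp = default_ramp(),
      episode_persistence = 0.5, episode_sd = 1.5,
      ddd_mu = log(5), ddd_sigma = 0.6,
      omission_base = 0.3, omission_drinking = 0.6
    )
  )
}

#' Configure a synthetic patient archetype
#'
#' Builds a generator configuration for one of five behavioral archetypes
#' (abstinent, controlled, weekend_binger, periodic_heavy, chaotic). A
#' latent AR(1) state plus additive weekday, ISO-week and treatment-time
#' logits drive the daily drinking probability; drinking days draw a
#' lognormal drinks-per-drinking-day (DDD) value and raise omission
#' probabilities. Any preset field can be overridden by name.
#'
#' @param name Archetype name.
#' @param n_days Monitored days (default 180).
#' @param tests_per_day Scheduled tests per day, 2-5 (default 3).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param start_date First monitored date (default a Monday, "2023-01-02").
#' @param ... Overrides of preset fields: `base_logit`, `weekday_logits`
#'   (named length-7), `week_logits` (length 53), `ramp` (data.frame
#'   `day`/`logit` knots, linearly interpolated), `episode_persistence`
#'   (AR(1) coefficient in \[0, 1)), `episode_sd` (stationary sd of the
#'   latent state, logits), `ddd_mu`, `ddd_sigma`, `omission_base`,
#'   `omission_drinking`.
#' @return An object of class `archetype_config`.
#' @export
archetype_config <- function(name = ARCHETYPES, n_days = 180, tests_per_day = 3,
                             seed = 1, start_date = as.Date("2023-01-02"), ...) {
  name <- match.arg(name)
  cfg <- archetype_presets()[[name]]
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop_validation("unknown config fields: %s", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  cfg$name <- name
  cfg$n_days <- as.integer(n_days)
  cfg$tests_per_day <- as.integer(tests_per_day)
  cfg$seed <- seed
  cfg$start_date <- as.Date(start_date)
  if (cfg$n_days < 1) stop_validation("n_days must be >= 1")
  if (cfg$tests_per_day < 2 || cfg$tests_per_day > 5) {
    stop_validation("tests_per_day must be in 2..5")
  }
  if (cfg$episode_persistence < 0 || cfg$episode_persistence >= 1) {
    stop_validation("episode_persistence must be in [0, 1)")
  }
  for (p in c("omission_base", "omission_drinking")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop_validation("%s must be in [0, 1]", p)
  }
  if (length(cfg$weekday_logits) != 7) stop_validation("weekday_logits must have length 7")
  if (length(cfg$week_logits) != 53) stop_validation("week_logits must have length 53")
  structure(cfg, class = "archetype_config")
}

#' Simulate one patient's test log and ground truth
#'
#' Draws the latent drinking course and emits (a) the observable scheduled
#' test log (windows, performed timestamps, BrAC values, omissions) and (b)
#' the per-day ground truth: the drinking flag, true DDD, the recorded DDD
#' (reported only on days with at least one performed test: the drawn value
#' on drinking days, 0 on sober days), and a pseudo-PEth built as a trailing
#' 21-day mean of true daily drinks times a calibration constant plus noise
#' (mirroring the slow kinetics of the blood biomarker).
#'
#' Sober tests draw BrAC from a half-normal with a BAC-equivalent median of
#' about 0.006 per mille; drinking days place a BAC above the 0.05 per mille
#' threshold at the last test window and, with probability 0.5, at other
#' windows in the later half of the day.
#'
#' @param config An [archetype_config()].
#' @param patient_id Identifier for the emitted rows.
#' @return List with `tests` (test-log tibble) and `truth` (tibble
#'   `patient_id`, `date`, `treatment_day`, `drank`, `ddd_true`, `ddd`,
#'   `peth_umol_l`).
#' @export
simulate_patient <- function(config, patient_id = "P001") {
  if (!inherits(config, "archetype_config")) {
    stop_validation("config must be an archetype_config")
  }
  set.seed(config$seed)
  n <- config$n_days
  m <- config$tests_per_day
  dates <- config$start_date + 0:(n - 1)
  wd <- as.integer(strftime(dates, "%u"))
  wk <- iso_week_of(dates)
  ramp <- stats::approx(config$ramp$day, config$ramp$logit, xout = 0:(n - 1),
                        rule = 2)$y
  rho <- config$episode_persistence
  e <- stats::rnorm(n)
  z <- numeric(n)
  z[1] <- config$episode_sd * e[1]
  if (n > 1) {
    z[-1] <- as.numeric(stats::filter(
      config$episode_sd * sqrt(1 - rho^2) * e[-1], rho,
      method = "recursive", init = z[1]
    ))
  }
  eta <- config$base_logit + config$weekday_logits[wd] + config$week_logits[wk] +
    ramp + z
  drink <- stats::runif(n) < stats::plogis(eta)
  ddd_true <- ifelse(drink, stats::rlnorm(n, config$ddd_mu, config$ddd_sigma), 0)

  hrs <- schedule_hours(m)
  day_idx <- rep(seq_len(n), each = m)
  test_idx <- rep(seq_len(m), times = n)
  window_start <- as.POSIXct(dates[day_idx], tz = "UTC") + (hrs[test_idx] - 0.5) * 3600
  window_end <- window_start + 3600
  p_omit <- ifelse(drink[day_idx], config$omission_drinking, config$omission_base)
  omitted <- stats::runif(n * m) < p_omit
  positive <- drink[day_idx] &
    (test_idx == m | (test_idx > m / 2 & stats::runif(n * m) < 0.5))
  bac_pos <- 0.05 + (0.05 + 0.03 * ddd_true[day_idx]) *
    stats::rlnorm(n * m, 0, 0.4)
  brac <- ifelse(positive, pmin(bac_pos, 3.5) / 2,
                 abs(stats::rnorm(n * m, 0, 0.00445)))
  performed_at <- window_start + stats::runif(n * m) * 3600
  tests <- tibble::tibble(
    patient_id = patient_id,
    window_start = window_start,
    window_end = window_end,
    performed_at = as.POSIXct(ifelse(omitted, NA_real_, as.numeric(performed_at)),
                              origin = "1970-01-01", tz = "UTC"),
    brac_permille = ifelse(omitted, NA_real_, brac)
  )
  any_performed <- tapply(!omitted, day_idx, any)

  w <- 21
  csum <- cumsum(ddd_true)
  lag_csum <- c(rep(0, min(w, n)), csum[seq_len(max(0, n - w))])
  trail_mean <- (csum - lag_csum) / pmin(seq_len(n), w)
  peth <- pmax(0, 0.35 * trail_mean + stats::rnorm(n, 0, 0.05))

  truth <- tibble::tibble(
    patient_id = patient_id,
    date = dates,
    treatment_day = 0:(n - 1),
    drank = as.integer(drink),
    ddd_true = ddd_true,
    ddd = ifelse(as.logical(any_performed), ddd_true, NA_real_),
    peth_umol_l = peth
  )
  list(tests = tests, truth = truth)
}

#' Simulate a cohort with an archetype mix
#'
#' Per-patient seeds derive from the master seed by the counter rule
#' `patient_seed = (seed + 48271 * i) mod (2^31 - 1)` for patient index
#' `i = 1..n`, so cohorts are reproducible under partial regeneration.
#' Archetype counts follow the mix proportions (largest-remainder rounding,
#' assigned in mix order).
#'
#' @param n_patients Number of patients (>= 1).
#' @param mix Named numeric vector of archetype proportions summing to 1,
#'   e.g. `c(weekend_binger = 0.5, abstinent = 0.5)`.
#' @param seed Master seed.
#' @param n_days,tests_per_day,start_date Passed to every patient's config.
#' @param ... Further [archetype_config()] overrides applied to every
#'   patient.
#' @return List with `tests` (cohort test log), `truth` (per-day ground
#'   truth incl. recorded DDD and pseudo-PEth), and `archetypes` (tibble
#'   `patient_id`, `archetype`, `seed`).
#' @export
simulate_cohort <- function(n_patients, mix = c(weekend_binger = 1), seed = 1,
                            n_days = 180, tests_per_day = 3,
                            start_date = as.Date("2023-01-02"), ...) {
  if (length(n_patients) != 1 || n_patients < 1) {
    stop_validation("n_patients must be a positive integer")
  }
  if (length(mix) == 0) stop_validation("archetype mix must be non-empty")
  if (is.null(names(mix)) || !all(names(mix) %in% ARCHETYPES)) {
    stop_validation("mix must be named with archetypes: %s",
                    paste(ARCHETYPES, collapse = ", "))
  }
  if (abs(sum(mix) - 1) > 1e-8) stop_validation("mix proportions must sum to 1")
  counts <- diff(c(0, round(cumsum(mix) * n_patients)))
  archetype <- rep(names(mix), counts)
  ids <- sprintf("P%03d", seq_len(n_patients))
  seeds <- (seed + 48271 * seq_len(n_patients)) %% 2147483647
  sims <- lapply(seq_len(n_patients), function(i) {
    cfg <- archetype_config(archetype[i], n_days = n_days,
                            tests_per_day = tests_per_day, seed = seeds[i],
                            start_date = start_date, ...)
    simulate_patient(cfg, patient_id = ids[i])
  })
  list(
    tests = dplyr::bind_rows(lapply(sims, `[[`, "tests")),
    truth = dplyr::bind_rows(lapply(sims, `[[`, "truth")),
    archetypes = tibble::tibble(patient_id = ids, archetype = archetype,
                                seed = seeds)
  )
}

#' Extract the observable covariate table from simulation truth
#'
#' @param truth Truth tibble from [simulate_cohort()].
#' @return Tibble `patient_id`, `date`, `ddd`, `peth_umol_l` suitable for
#'   [aggregate_days()] and [scan_thresholds()].
#' @export
truth_covariates <- function(truth) {
  truth[c("patient_id", "date", "ddd", "peth_umol_l")]
}
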