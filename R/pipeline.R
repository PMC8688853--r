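# End-to-end pipeline: test log -> day table -> AMI family -> REI -> events
# -> summaries -> periodicity tables, with deterministic CSV export.

#' Pipeline configuration
#'
#' Collects the defaults of the whole analysis: the AMI family (6, 12, 21,
#' 45), the REI pair (45/6), the REI threshold (0.8), the BAC drinking
#' threshold (0.05 per mille), the minimum event length kept in summaries,
#' and the treatment-bin width (30 days).
#'
#' @param alphas AMI family names N (alpha = N/100).
#' @param rei_pair Numerator/denominator names; must be among `alphas`.
#' @param threshold REI threshold for event detection (> 0).
#' @param bac_threshold BAC drinking threshold, per mille.
#' @param min_event_length Minimum event length (days) kept in summaries and
#'   plots; 1 keeps all events.
#' @param bin_width Treatment-day bin width for periodicity tables.
#' @param rei_cap Cap applied to the REI ratio.
#' @param tests_per_day Schedule used when expanding missing days (`NULL` =
#'   infer per patient).
#' @param decay_exponent Omission-decay shape, see [ami_params()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(alphas = c(6, 12, 21, 45), rei_pair = c(45, 6),
                            threshold = 0.8, bac_threshold = 0.05,
                            min_event_length = 1, bin_width = 30,
                            rei_cap = 10, tests_per_day = NULL,
                            decay_exponent = 1) {
  if (!all(rei_pair %in% alphas)) {
    stop_validation("rei_pair alphas must be among the computed alphas")
  }
  if (threshold <= 0) stop_validation("threshold must be positive")
  structure(
    list(alphas = alphas, rei_pair = rei_pair, threshold = threshold,
         bac_threshold = bac_threshold, min_event_length = min_event_length,
         bin_width = bin_width, rei_cap = rei_cap,
         tests_per_day = tests_per_day, decay_exponent = decay_exponent),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' File values override the defaults of [pipeline_config()]; unknown keys
#' are an error. The effective configuration is echoed via `message()`.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop_validation("unknown config keys: %s", paste(unknown, collapse = ", "))
  }
  cfg <- do.call(pipeline_config, vals)
  message("config: ", paste(sprintf("%s=%s", names(vals),
                                    vapply(vals, function(v) paste(v, collapse = ","), "")),
                            collapse = " "))
  cfg
}

#' Run the full biomarker pipeline
#'
#' Deterministically derives every analysis table from a test log: the
#' per-day records, the AMI family, the REI series, the exacerbation events,
#' per-patient summaries, the cohort day table, and %EE periodicity tables
#' by weekday, ISO week and treatment bin.
#'
#' @param tests Validated test-log tibble (see [read_test_log()]).
#' @param covariates Optional per-day covariates (DDD, PEth).
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage row-count messages?
#' @return A named list (`days`, `ami`, `rei`, `events`, `summary`,
#'   `cohort_days`, `periodicity`) of tibbles; `periodicity` is itself a
#'   named list of grouped %EE tables.
#' @export
run_pipeline <- function(tests, covariates = NULL, config = pipeline_config(),
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  params <- ami_params(bac_threshold = config$bac_threshold,
                       decay_exponent = config$decay_exponent)
  days <- aggregate_days(tests, covariates, params = params,
                         tests_per_day = config$tests_per_day)
  say("days: %d rows, %d patients", nrow(days), length(unique(days$patient_id)))
  ami <- compute_ami_family(days, config$alphas)
  say("ami: %d rows, alphas %s", nrow(ami), paste(config$alphas, collapse = "/"))
  rei <- add_rei(ami, config$rei_pair, cap = config$rei_cap)
  say("rei: %d rows (pair %s)", nrow(rei), paste(config$rei_pair, collapse = "/"))
  events <- detect_cohort_events(rei, config$threshold, config$min_event_length)
  say("events: %d (threshold %.2f, min length %d)", nrow(events),
      config$threshold, config$min_event_length)
  summary <- summarize_cohort(days, ami, events,
                              min_event_length = config$min_event_length)
  cohort_days <- cohort_day_table(days, events, bin_width = config$bin_width)
  periodicity <- lapply(
    stats::setNames(nm = c("weekday", "iso_week", "treatment_bin")),
    function(f) percent_ee_by(cohort_days, f)
  )
  say("summary: %d patients; cohort %%EE = %.1f", nrow(summary),
      100 * mean(cohort_days$in_ee))
  list(days = days, ami = ami, rei = rei, events = events, summary = summary,
       cohort_days = cohort_days, periodicity = periodicity)
}

#' Write a pipeline bundle to CSV files
#'
#' Writes `days.csv`, `ami.csv`, `rei.csv`, `events.csv`, `summary.csv`,
#' `cohort_days.csv` and `percent_ee_<factor>.csv` into a directory;
#' re-running on the same inputs produces byte-identical files.
#'
#' @param bundle List from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("days", "ami", "rei", "events", "summary", "cohort_days")) {
    readr::write_csv(bundle[[nm]], file.path(dir, paste0(nm, ".csv")), na = "")
  }
  for (f in names(bundle$periodicity)) {
    readr::write_csv(bundle$periodicity[[f]],
                     file.path(dir, paste0("percent_ee_", f, ".csv")), na = "")
  }
  invisible(dir)
}
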