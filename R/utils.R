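# Internal helpers shared across modules.

#' Signal a validation error
#'
#' All input-contract violations raise a condition of class
#' `amirei_validation_error` so callers (and the command-line wrapper, which
#' maps them to exit code 1) can distinguish bad input from internal faults.
#'
#' @param msg Message, `sprintf()`-style.
#' @param ... Values interpolated into `msg`.
#' @noRd
stop_validation <- function(msg, ...) {
  if (length(list(...)) > 0) msg <- sprintf(msg, ...)
  stop(structure(
    list(message = msg, call = sys.call(-1)),
    class = c("amirei_validation_error", "error", "condition")
  ))
}

# weekday levels used everywhere; %u gives 1 = Monday
WEEKDAY_LEVELS <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")

weekday_of <- function(date) {
  factor(WEEKDAY_LEVELS[as.integer(strftime(date, "%u"))], levels = WEEKDAY_LEVELS)
}

iso_week_of <- function(date) {
  as.integer(strftime(date, "%V"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
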