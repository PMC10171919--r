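# Shared constants and small validators.

# Single documented time-unit conversion point: evidence synthesis works in
# months, the cohort model on 28-day cycles.
DAYS_PER_MONTH <- 365.25 / 12   # 30.4375
CYCLE_DAYS <- 28
CYCLE_MONTHS <- CYCLE_DAYS / DAYS_PER_MONTH
CYCLE_YEARS <- CYCLE_DAYS / 365.25

abort_config <- function(msg) abort(msg, class = "immunocea_config_error")
abort_validation <- function(msg) abort(msg, class = "immunocea_validation_error")

check_probability <- function(x, name, allow_one = TRUE) {
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || !all(hi_ok)) {
    abort_config(sprintf("`%s` must be a probability in [0,%s]", name,
                         if (allow_one) "1]" else "1)"))
  }
  invisible(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort_config(sprintf("`%s` must be a positive finite number", name))
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0)) {
    abort_config(sprintf("`%s` must be nonnegative", name))
  }
  invisible(x)
}

#' Discount factor at a point in time
#'
#' Discrete annual rate applied continuously in cycle time, `(1 + r)^(-t)`,
#' evaluated at the start of each cycle by default.
#'
#' @param t_years time in years.
#' @param rate annual discount rate (0.05 by default elsewhere).
#' @return numeric vector of discount factors.
#' @keywords internal
discount_factor <- function(t_years, rate) {
  (1 + rate)^(-t_years)
}
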