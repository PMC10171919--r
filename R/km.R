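# Kaplan-Meier estimation (weighted product-limit via the survival package)
# and the digitized-curve container consumed by pseudo-IPD reconstruction.

#' Digitized Kaplan-Meier curve with numbers-at-risk table
#'
#' Container for published aggregate survival evidence: curve coordinates read
#' off a figure plus the numbers-at-risk table printed beneath it. Survival is
#' clamped to be nonincreasing (the number of repaired points is recorded in
#' `attr(, "repairs")`); digitized times are taken as exact.
#'
#' @param curve data frame with columns `time`, `survival`.
#' @param risk_table data frame with columns `time`, `n_risk`.
#' @param total_events optional total event count, if published.
#' @return a `digitized_km` object.
#' @export
digitized_km <- function(curve, risk_table, total_events = NULL) {
  curve <- as_tibble(curve)[c("time", "survival")]
  risk_table <- as_tibble(risk_table)[c("time", "n_risk")]
  if (nrow(curve) < 2) abort_validation("need at least 2 curve points")
  curve <- arrange(curve, .data$time)
  if (curve$time[1] > 0) {
    curve <- bind_rows(tibble(time = 0, survival = 1), curve)
  }
  if (any(curve$survival < 0 | curve$survival > 1)) {
    abort_validation("survival values must lie in [0, 1]")
  }
  clamped <- cummin(curve$survival)
  repairs <- sum(clamped != curve$survival)
  curve$survival <- clamped
  risk_table <- arrange(risk_table, .data$time)
  if (any(diff(risk_table$n_risk) > 0)) {
    abort_validation("risk table is inconsistent: n_risk must be nonincreasing in time")
  }
  if (any(risk_table$n_risk < 0)) abort_validation("n_risk must be nonnegative")
  structure(list(curve = curve, risk_table = risk_table,
                 total_events = total_events),
            class = "digitized_km", repairs = repairs)
}

#' @export
#' @exportS3Method
print.digitized_km <- function(x, ...) {
  cat(sprintf("<digitized_km> %d curve points over [%g, %g] months, %d risk-table rows\n",
              nrow(x$curve), min(x$curve$time), max(x$curve$time), nrow(x$risk_table)))
  if (!is.null(x$total_events)) cat(sprintf("  total events: %d\n", x$total_events))
  invisible(x)
}

#' Write / read a digitized curve as a pair of CSV files
#'
#' @param dk a [digitized_km()].
#' @param curve_path,risk_path file paths for the curve (`time,survival`) and
#'   risk table (`time,n_risk`) CSVs.
#' @param total_events optional event total when reading.
#' @return `read_digitized_km` returns a `digitized_km`.
#' @export
write_digitized_km <- function(dk, curve_path, risk_path) {
  readr::write_csv(dk$curve, curve_path)
  readr::write_csv(dk$risk_table, risk_path)
  invisible(dk)
}

#' @rdname write_digitized_km
#' @export
read_digitized_km <- function(curve_path, risk_path, total_events = NULL) {
  digitized_km(readr::read_csv(curve_path, show_col_types = FALSE),
               readr::read_csv(risk_path, show_col_types = FALSE),
               total_events = total_events)
}

resolve_endpoint_columns <- function(records, endpoint) {
  tcol <- paste0(endpoint, "_time")
  ecol <- paste0(endpoint, "_event")
  if (!tcol %in% names(records) && "time" %in% names(records)) {
    tcol <- "time"; ecol <- "event"
  }
  if (!all(c(tcol, ecol) %in% names(records))) {
    abort_validation(sprintf("records lack columns for endpoint '%s'", endpoint))
  }
  list(time = records[[tcol]], event = records[[ecol]])
}

#' Kaplan-Meier estimate of a survival endpoint
#'
#' Product-limit estimate with optional nonnegative per-subject weights
#' (weighted risk sets and event counts, as used after matching-adjusted
#' reweighting). Greenwood variance is reported per step.
#'
#' @param records subject-level data with `<endpoint>_time` / `<endpoint>_event`
#'   columns (or plain `time` / `event`); a `.maic_weight` column, if present,
#'   is used when `weights` is `NULL`.
#' @param endpoint `"os"` or `"pfs"`.
#' @param weights optional nonnegative weights, one per record.
#' @return a `km_fit`: tibble of steps (`time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, `greenwood_var`) with `S(0) = 1` as first row.
#' @export
km_estimate <- function(records, endpoint = c("os", "pfs"), weights = NULL) {
  endpoint <- arg_match(endpoint)
  cols <- resolve_endpoint_columns(records, endpoint)
  if (is.null(weights) && ".maic_weight" %in% names(records)) {
    weights <- records$.maic_weight
  }
  if (is.null(weights)) weights <- rep(1, nrow(records))
  if (any(weights < 0)) abort_validation("weights must be nonnegative")
  if (sum(weights) <= 0) abort_validation("weights must not all be zero")
  if (length(cols$time) == 0) abort_validation("need at least one observation")

  df <- data.frame(time = cols$time, event = cols$event, w = weights)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = df,
                          weights = df$w, conf.type = "none")
  steps <- tibble(
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    n_censor = sf$n.censor, survival = sf$surv
  )
  # Greenwood: var(S) = S^2 * cumsum(d / (n (n - d)))
  incr <- ifelse(steps$n_risk > steps$n_event,
                 steps$n_event / (steps$n_risk * (steps$n_risk - steps$n_event)), 0)
  steps$greenwood_var <- steps$survival^2 * cumsum(incr)
  steps <- bind_rows(
    tibble(time = 0, n_risk = sum(weights), n_event = 0, n_censor = 0,
           survival = 1, greenwood_var = 0),
    filter(steps, .data$time > 0)
  )
  structure(steps, class = c("km_fit", class(steps)),
            endpoint = endpoint, n = nrow(records), sum_w = sum(weights))
}

#' Evaluate a step survival function
#'
#' Right-continuous evaluation of a `km_fit` (or any tibble with `time` and
#' `survival`) at arbitrary times; `S = 1` before the first recorded time.
#'
#' @param s a `km_fit`.
#' @param t times at which to evaluate.
#' @return numeric vector of survival probabilities.
#' @export
survival_step_at <- function(s, t) {
  idx <- findInterval(t, s$time)
  ifelse(idx == 0, 1, s$survival[pmax(idx, 1)])
}

#' Median survival time of a step function
#'
#' Smallest time at which the curve reaches 0.5 or below; `NA` (the
#' "not reached" flag, as reported for immature curves with a plateau above
#' 0.5) when the curve never crosses it.
#'
#' @param s a `km_fit`.
#' @return months, or `NA_real_` when the median is not reached.
#' @export
median_survival <- function(s) {
  hit <- which(s$survival <= 0.5)
  if (length(hit) == 0) return(NA_real_)
  s$time[hit[1]]
}

#' @export
#' @exportS3Method
tidy.km_fit <- function(x, ...) as_tibble(unclass(x))

#' @export
#' @exportS3Method
glance.km_fit <- function(x, ...) {
  tibble(endpoint = attr(x, "endpoint"), n = attr(x, "n"),
         events = sum(x$n_event), median = median_survival(x))
}

#' Plot a Kaplan-Meier step curve
#'
#' @param object a `km_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
#' @exportS3Method
autoplot.km_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability") +
    ggplot2::theme_minimal()
}
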