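# Three-state (PFS, PD, Death) cohort model on 28-day cycles. The two
# extrapolated curves drive the transitions: death risk is state-independent
# (derived from the OS curve, applied in both alive states), progression is
# whatever part of the PFS curve's per-cycle drop death does not explain.
# With that reading the trace reproduces both input curves exactly on cycle
# boundaries whenever no clamping fires (partitioned-survival equivalence).

#' Derive per-cycle transition probabilities from two cycle-survival curves
#'
#' `p_death_j = 1 - S_os[j+1] / S_os[j]` applies in both PFS and PD;
#' `p_prog_j = max(0, (1 - S_pfs[j+1] / S_pfs[j]) - p_death_j)`. Curve
#' crossings (`S_pfs > S_os`, possible after independent extrapolation) are
#' repaired by `S_pfs := min(S_pfs, S_os)` first; repair and clamping counts
#' are recorded in `attr(, "diagnostics")`. The schedule is truncated where
#' the OS curve reaches zero.
#'
#' @param s_pfs,s_os `cycle_survival` objects on the same grid.
#' @return a `transition_schedule` tibble: `cycle` (1-based), `p_death`,
#'   `p_prog`.
#' @export
derive_transitions <- function(s_pfs, s_os) {
  if (nrow(s_pfs) != nrow(s_os)) abort_validation("cycle grids differ in length")
  pfs <- s_pfs$survival
  os <- s_os$survival
  crossings <- sum(pfs > os + 1e-12)
  pfs <- pmin(pfs, os)

  alive <- which(os[-length(os)] > 0)
  j <- seq_len(if (length(alive)) max(alive) else 0)
  p_death <- 1 - os[j + 1] / os[j]
  raw_prog <- ifelse(pfs[j] > 0, 1 - pfs[j + 1] / pfs[j], 0) - p_death
  clamped <- sum(raw_prog < -1e-12 & pfs[j] > 0)
  p_prog <- pmax(0, raw_prog) * ifelse(pfs[j] > 0, 1, 0)

  structure(tibble(cycle = j, p_death = p_death, p_prog = p_prog),
            class = c("transition_schedule", class(tibble())),
            diagnostics = list(pfs_os_crossings = crossings,
                               negative_prog_clamped = clamped))
}

#' Run the three-state cohort model
#'
#' The cohort starts fully in PFS. Each cycle, the PFS occupancy loses
#' `p_death + p_prog` (to Death and PD) and the PD occupancy loses `p_death`;
#' Death is absorbing. In `"lifetime"` mode the trace stops once more than
#' 99% of the cohort has died (or the schedule is exhausted); `"fixed"` mode
#' stops after `n_cycles` cycles (the 36-month scenario uses 39 complete
#' 28-day cycles).
#'
#' @param ts a [derive_transitions()] schedule.
#' @param horizon `"lifetime"` or `"fixed"`.
#' @param n_cycles cycle count for `"fixed"` mode.
#' @return a `cohort_trace` tibble: `cycle` (0-based), `time_years`,
#'   `occ_pfs`, `occ_pd`, `occ_death`, `new_deaths` (mass entering Death
#'   during the cycle that ends at this boundary).
#' @export
run_cohort <- function(ts, horizon = c("lifetime", "fixed"), n_cycles = NULL) {
  horizon <- arg_match(horizon)
  if (horizon == "fixed") {
    if (is.null(n_cycles) || n_cycles <= 0) abort_config("`n_cycles` must be a positive count")
    n_use <- min(n_cycles, nrow(ts))
  } else {
    n_use <- nrow(ts)
  }
  p_death <- ts$p_death[seq_len(n_use)]
  p_prog <- ts$p_prog[seq_len(n_use)]

  # closed form of the recursion: death risk is state-independent, so the
  # alive fraction is a cumulative product and PFS occupancy another
  occ_pfs <- c(1, cumprod(1 - p_death - p_prog))
  alive <- c(1, cumprod(1 - p_death))
  occ_pfs <- pmax(occ_pfs, 0)
  occ_pd <- pmax(alive - occ_pfs, 0)
  occ_death <- 1 - alive
  new_deaths <- c(0, -diff(alive))

  if (horizon == "lifetime") {
    stop_at <- which(occ_death > 0.99)
    if (length(stop_at) > 0) {
      keep <- seq_len(stop_at[1])
      occ_pfs <- occ_pfs[keep]; occ_pd <- occ_pd[keep]
      occ_death <- occ_death[keep]; new_deaths <- new_deaths[keep]
    }
  }
  n_b <- length(occ_pfs)
  structure(tibble(
    cycle = 0:(n_b - 1),
    time_years = (0:(n_b - 1)) * CYCLE_YEARS,
    occ_pfs = occ_pfs, occ_pd = occ_pd, occ_death = occ_death,
    new_deaths = new_deaths
  ), class = c("cohort_trace", class(tibble())))
}

#' @export
#' @exportS3Method
glance.cohort_trace <- function(x, ...) {
  tibble(cycles = nrow(x) - 1,
         final_dead = x$occ_death[nrow(x)],
         conservation_error = max(abs(x$occ_pfs + x$occ_pd + x$occ_death - 1)))
}

#' Plot state occupancy over time
#'
#' @param object a `cohort_trace`.
#' @param ... unused.
#' @return a stacked-area ggplot of PFS / PD / Death occupancy.
#' @export
#' @exportS3Method
autoplot.cohort_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("occ_pfs", "occ_pd", "occ_death"),
                              names_to = "state", values_to = "occupancy")
  long$state <- factor(long$state, levels = c("occ_death", "occ_pd", "occ_pfs"),
                       labels = c("Death", "Progressed", "Progression-free"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_years, y = .data$occupancy,
                                     fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Time (years)", y = "Cohort occupancy", fill = NULL) +
    ggplot2::theme_minimal()
}
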