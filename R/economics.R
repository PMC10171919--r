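# Cost and utility layer: attaches the transcribed cost/utility/adverse-event
# parameter tables to a cohort trace and computes discounted costs,
# life-years, QALYs and the ICER. All monetary values are 2022 US dollars
# (the source analysis' conversion, 6.7413 yuan per dollar); no re-inflation.

#' Load the packaged economic parameter tables
#'
#' Reads the versioned fixture files (per-arm cost table, adverse-event table
#' with grade >= 3 incidences / management costs / disutilities, utility
#' sets, drug dosing rules) and bundles them with the analysis switches.
#'
#' @param dir directory holding `costs.csv`, `adverse_events.csv`,
#'   `utilities.csv`, `drugs.csv` (defaults to the package fixtures).
#' @param utility_set `"base"` (0.84 / 0.57), `"astrum"` (0.94 / 0.87) or
#'   `"correct"` (0.73 / 0.59).
#' @param discount_cost,discount_qaly annual discount rates (5% base case).
#' @param wtp willingness-to-pay threshold, $/QALY (triple GDP per capita).
#' @param ae_horizon_months per-arm exposure horizon used to convert periodic
#'   adverse-event incidences to per-cycle probabilities (median treatment
#'   duration; 9.83 / 3.2 months).
#' @return an `econ_inputs` object.
#' @export
load_econ_inputs <- function(dir = system.file("extdata", package = "immunocea"),
                             utility_set = "base",
                             discount_cost = 0.05, discount_qaly = 0.05,
                             wtp = 36036,
                             ae_horizon_months = c(serplulimab = 9.83,
                                                   regorafenib = 3.2)) {
  costs_raw <- readr::read_csv(file.path(dir, "costs.csv"), show_col_types = FALSE)
  ae <- readr::read_csv(file.path(dir, "adverse_events.csv"), show_col_types = FALSE)
  utl <- readr::read_csv(file.path(dir, "utilities.csv"), show_col_types = FALSE)
  drugs <- readr::read_csv(file.path(dir, "drugs.csv"), show_col_types = FALSE)

  if (!utility_set %in% utl$set) abort_config(sprintf("unknown utility set '%s'", utility_set))
  urow <- utl[utl$set == utility_set, ]
  costs <- list(
    serplulimab = setNames(costs_raw$serplulimab, costs_raw$parameter),
    regorafenib = setNames(costs_raw$regorafenib, costs_raw$parameter)
  )
  for (arm in names(costs)) check_nonnegative(costs[[arm]], paste0("costs$", arm))
  check_probability(ae$incidence, "ae incidence")
  check_probability(urow$u_pfs, "u_pfs"); check_probability(urow$u_pd, "u_pd")

  structure(list(
    costs = costs, ae = as_tibble(ae), drugs = as_tibble(drugs),
    u_pfs = urow$u_pfs, u_pd = urow$u_pd, utility_set = utility_set,
    discount_cost = discount_cost, discount_qaly = discount_qaly,
    wtp = wtp, ae_horizon_months = ae_horizon_months
  ), class = "econ_inputs")
}

#' Drug acquisition cost for one model cycle
#'
#' Pure function implementing the dosing rules. Serplulimab: 3 mg/kg at the
#' reference 65 kg weight rounds up to whole 100 mg vials (2 vials of
#' $828.92), twice per 4-week cycle, zero beyond the 2-year stopping rule
#' (26 cycles). Regorafenib: 21 daily 160 mg doses of $102.34 per 28-day
#' cycle, for as long as the patient remains progression-free. (The per-cycle
#' constants used in [cycle_costs()] come from the transcribed cost table;
#' this function recomputes them from first principles.)
#'
#' @param arm `"serplulimab"` or `"regorafenib"`.
#' @param cycle_index 0-based cycle index.
#' @param inputs an `econ_inputs` object.
#' @return cost in USD for that cycle while on treatment.
#' @export
drug_cost_per_cycle <- function(arm = c("serplulimab", "regorafenib"),
                                cycle_index, inputs = load_econ_inputs()) {
  arm <- arg_match(arm)
  if (any(cycle_index < 0)) abort_config("`cycle_index` must be >= 0")
  d <- inputs$drugs[inputs$drugs$arm == arm, ]
  if (arm == "serplulimab") {
    vials <- ceiling(d$mg_per_kg * d$weight_kg / d$vial_mg)
    per_cycle <- vials * d$unit_price * d$admins_per_cycle
    ifelse(cycle_index < d$max_cycles, per_cycle, 0)
  } else {
    rep(d$daily_doses_per_cycle * d$unit_price, length(cycle_index))
  }
}

#' Convert a trial-horizon incidence into a per-cycle probability
#'
#' Incidence -> constant rate -> per-cycle probability:
#' `r = -log(1 - incidence) / horizon` (per month) and
#' `p = 1 - exp(-r * cycle / 30.4375)`.
#'
#' @param incidence cumulative incidence over `horizon`.
#' @param horizon_months exposure horizon in months.
#' @param cycle_days cycle length in days (28).
#' @return per-cycle probability.
#' @export
rate_convert <- function(incidence, horizon_months, cycle_days = CYCLE_DAYS) {
  check_probability(incidence, "incidence")
  check_positive(horizon_months, "horizon_months")
  r <- -log(1 - incidence) / horizon_months
  1 - exp(-r * cycle_days / DAYS_PER_MONTH)
}

# occupancy rows that open a cycle (all boundaries but the last), with the
# deaths occurring during that cycle
cycle_frame <- function(trace) {
  n <- nrow(trace)
  if (n < 2) abort_validation("trace has no complete cycle")
  tibble(
    cycle = trace$cycle[-n],
    t_years = trace$time_years[-n],
    occ_pfs = trace$occ_pfs[-n],
    occ_pd = trace$occ_pd[-n],
    deaths = trace$new_deaths[-1]
  )
}

monitor_cost_at <- function(costs, t_years) {
  case_when(
    t_years < 3 ~ costs[["monitor_pfs_y1_3"]],
    t_years < 5 ~ costs[["monitor_pfs_y4_5"]],
    TRUE ~ costs[["monitor_pfs_gt5"]]
  )
}

#' Undiscounted per-cycle cost streams for one arm
#'
#' Cycle 0 carries diagnosis plus the expected one-off adverse-event
#' management cost. Every cycle adds progression-free occupancy times (drug +
#' monitoring band + administration + hospitalization), progressed occupancy
#' times (monitoring + administration + hospitalization + subsequent
#' treatment), the expected periodic adverse-event cost, and end-of-life cost
#' on the mass entering death.
#'
#' @param trace a `cohort_trace`.
#' @param inputs an `econ_inputs`.
#' @param arm arm name.
#' @return tibble of per-cycle component streams and their `total`.
#' @export
cycle_costs <- function(trace, inputs, arm = c("serplulimab", "regorafenib")) {
  arm <- arg_match(arm)
  cs <- inputs$costs[[arm]]
  ae <- filter(inputs$ae, .data$arm == !!arm)
  fr <- cycle_frame(trace)

  drug_stream <- if (arm == "serplulimab") {
    cap <- inputs$drugs$max_cycles[inputs$drugs$arm == "serplulimab"]
    ifelse(fr$cycle < cap, cs[["drug_per_cycle"]], 0) * fr$occ_pfs
  } else {
    cs[["drug_per_cycle"]] * fr$occ_pfs
  }

  one_off <- filter(ae, .data$kind == "one_off")
  periodic <- filter(ae, .data$kind == "periodic")
  p_periodic <- if (nrow(periodic) > 0) {
    rate_convert(periodic$incidence, inputs$ae_horizon_months[[arm]])
  } else numeric(0)

  out <- tibble(
    cycle = fr$cycle,
    t_years = fr$t_years,
    drug = drug_stream,
    diagnosis = ifelse(fr$cycle == 0, cs[["diagnosis"]], 0),
    monitoring = fr$occ_pfs * monitor_cost_at(cs, fr$t_years) +
      fr$occ_pd * cs[["monitor_pd"]],
    administration = fr$occ_pfs * cs[["admin_pfs"]] + fr$occ_pd * cs[["admin_pd"]],
    hospitalization = fr$occ_pfs * cs[["hosp_pfs"]] + fr$occ_pd * cs[["hosp_pd"]],
    subsequent = fr$occ_pd * cs[["subsequent_tx_per_cycle"]],
    ae_one_off = ifelse(fr$cycle == 0, sum(one_off$incidence * one_off$mgmt_cost), 0),
    ae_periodic = fr$occ_pfs * sum(p_periodic * periodic$mgmt_cost),
    end_of_life = fr$deaths * cs[["eol"]]
  )
  out$total <- rowSums(select(out, -"cycle", -"t_years"))
  out
}

#' Accumulate (discounted) life-years and QALYs over a trace
#'
#' Per cycle, the life-year contribution is
#' `(occ_pfs + occ_pd) * 28 / 365.25` years; the QALY contribution weights the
#' two alive states by their utilities and subtracts adverse-event
#' disutilities (one-off: incidence x disutility for one cycle at cycle 0;
#' periodic: converted per-cycle probability x disutility on the
#' progression-free occupancy). Discounting uses `(1 + r)^(-t)` at cycle
#' start.
#'
#' @param trace a `cohort_trace`.
#' @param inputs an `econ_inputs`.
#' @param arm arm name.
#' @param discount_rate annual rate for effects (defaults to the inputs').
#' @return one-row tibble: `ly`, `qaly`, `ly_disc`, `qaly_disc`.
#' @export
qaly_accumulate <- function(trace, inputs, arm = c("serplulimab", "regorafenib"),
                            discount_rate = NULL) {
  arm <- arg_match(arm)
  r <- discount_rate %||% inputs$discount_qaly
  ae <- filter(inputs$ae, .data$arm == !!arm)
  fr <- cycle_frame(trace)

  ly_c <- (fr$occ_pfs + fr$occ_pd) * CYCLE_YEARS
  q_c <- (fr$occ_pfs * inputs$u_pfs + fr$occ_pd * inputs$u_pd) * CYCLE_YEARS

  one_off <- filter(ae, .data$kind == "one_off")
  periodic <- filter(ae, .data$kind == "periodic")
  q_c[1] <- q_c[1] - sum(one_off$incidence * one_off$disutility) * CYCLE_YEARS
  if (nrow(periodic) > 0) {
    p_per <- rate_convert(periodic$incidence, inputs$ae_horizon_months[[arm]])
    q_c <- q_c - fr$occ_pfs * sum(p_per * periodic$disutility) * CYCLE_YEARS
  }

  df <- discount_factor(fr$t_years, r)
  tibble(ly = sum(ly_c), qaly = sum(q_c),
         ly_disc = sum(ly_c * df), qaly_disc = sum(q_c * df))
}

#' Evaluate one arm end to end
#'
#' @param trace a `cohort_trace` for the arm.
#' @param inputs an `econ_inputs`.
#' @param arm arm name.
#' @return one-row tibble of discounted and undiscounted totals.
#' @export
arm_result <- function(trace, inputs, arm = c("serplulimab", "regorafenib")) {
  arm <- arg_match(arm)
  cc <- cycle_costs(trace, inputs, arm)
  df_cost <- discount_factor(cc$t_years, inputs$discount_cost)
  eff <- qaly_accumulate(trace, inputs, arm)
  tibble(arm = arm,
         cost = sum(cc$total * df_cost),
         cost_undisc = sum(cc$total),
         ly = eff$ly_disc, qaly = eff$qaly_disc,
         ly_undisc = eff$ly, qaly_undisc = eff$qaly)
}

#' Incremental cost-effectiveness of intervention vs comparator
#'
#' @param intervention,comparator one-row tibbles from [arm_result()].
#' @param wtp willingness-to-pay threshold ($/QALY).
#' @return a `ce_result`: both arms plus `delta_cost`, `delta_qaly`, `icer`
#'   (NA with a `dominance` label when the ratio is undefined or dominated),
#'   and the cost-effectiveness verdict at `wtp`.
#' @export
compute_icer <- function(intervention, comparator, wtp = 36036) {
  dc <- intervention$cost - comparator$cost
  dq <- intervention$qaly - comparator$qaly
  dominance <- dplyr::case_when(
    dc < 0 && dq > 0 ~ "dominant",
    dc > 0 && dq < 0 ~ "dominated",
    dq == 0 ~ "undefined",
    .default = "none"
  )
  icer <- if (dominance == "none") dc / dq else NA_real_
  nmb <- wtp * dq - dc
  structure(list(
    arms = bind_rows(intervention, comparator),
    delta_cost = dc, delta_qaly = dq,
    delta_ly = intervention$ly - comparator$ly,
    icer = icer, dominance = dominance,
    wtp = wtp, nmb = nmb,
    cost_effective = (dominance == "dominant") ||
      (dominance == "none" && !is.na(icer) && dq > 0 && icer <= wtp) ||
      (dominance == "none" && dq < 0 && icer > wtp)
  ), class = "ce_result")
}

#' @export
#' @exportS3Method
print.ce_result <- function(x, ...) {
  cat("<ce_result>\n")
  print(mutate(x$arms, across(c("cost", "cost_undisc"), ~ round(.x, 2)),
               across(c("ly", "qaly", "ly_undisc", "qaly_undisc"), ~ round(.x, 3))))
  if (x$dominance == "none") {
    cat(sprintf("  ICER: %.2f $/QALY (delta cost %.2f, delta QALY %.3f)\n",
                x$icer, x$delta_cost, x$delta_qaly))
  } else {
    cat(sprintf("  %s (delta cost %.2f, delta QALY %.3f)\n",
                x$dominance, x$delta_cost, x$delta_qaly))
  }
  cat(sprintf("  %scost-effective at WTP %s $/QALY\n",
              if (x$cost_effective) "" else "NOT ", format(x$wtp, big.mark = ",")))
  invisible(x)
}

#' @export
#' @exportS3Method
tidy.ce_result <- function(x, ...) x$arms

#' @export
#' @exportS3Method
glance.ce_result <- function(x, ...) {
  tibble(delta_cost = x$delta_cost, delta_qaly = x$delta_qaly,
         delta_ly = x$delta_ly, icer = x$icer, dominance = x$dominance,
         wtp = x$wtp, nmb = x$nmb, cost_effective = x$cost_effective)
}
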