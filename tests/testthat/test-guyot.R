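test_that("digitized curves are validated and clamped to nonincreasing", {
  expect_error(
    digitized_km(curve = data.frame(time = c(0, 1), survival = c(1, 0.8)),
                 risk_table = data.frame(time = c(0, 1), n_risk = c(10, 12))),
    class = "immunocea_validation_error")
  dk <- digitized_km(curve = data.frame(time = c(0, 1, 2), survival = c(1, 0.7, 0.72)),
                     risk_table = data.frame(time = c(0, 2), n_risk = c(10, 5)))
  expect_equal(dk$curve$survival, c(1, 0.7, 0.7))
  expect_equal(attr(dk, "repairs"), 1)
})

test_that("reconstruction is exact when the curve and risk table are information-complete", {
  # known 20-subject cohort: events at distinct times, censorings between them
  time <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 1.5, 2.5, 4.5, 6.5, 8.5, 12, 12, 12, 12, 12)
  event <- c(rep(1, 10), rep(0, 10))
  rec <- records_from(time, event)
  km <- km_estimate(rec, "os")
  event_times <- km$time[km$n_event > 0]
  risk_times <- c(0, event_times)
  n_at_risk <- vapply(risk_times, function(tt) sum(time >= tt), numeric(1))
  dk <- digitized_km(
    curve = tibble::tibble(time = km$time, survival = km$survival),
    risk_table = tibble::tibble(time = risk_times, n_risk = n_at_risk),
    total_events = sum(event))
  out <- reconstruct_ipd(dk)
  expect_equal(sort(out$time[out$event == 1]), sort(time[event == 1]))
  expect_equal(sum(out$event == 0), sum(event == 0))
  expect_equal(nrow(out), 20)
})

test_that("reconstructed cohorts reproduce the digitized curve and its median", {
  cfg <- comparator_cohort_config(seed = 42, n = 500)
  dk <- generate_aggregate_trial(cfg, readoff_times = seq(0, 20, by = 0.5),
                                 risk_times = seq(0, 20, by = 2), keep_cohort = TRUE)
  out <- reconstruct_ipd(dk)
  km_out <- km_estimate(out, "os")
  sup_err <- max(abs(survival_step_at(km_out, dk$curve$time) - dk$curve$survival))
  expect_lt(sup_err, 0.02)
  km_hidden <- km_estimate(attr(dk, "cohort"), "os")
  expect_lt(abs(median_survival(km_out) - median_survival(km_hidden)), 0.5)
})

test_that("reconstruction error does not grow as the risk table gets denser", {
  cfg <- comparator_cohort_config(seed = 13, n = 300)
  sup_err_at <- function(risk_step) {
    dk <- generate_aggregate_trial(cfg, readoff_times = seq(0, 18, by = 1),
                                   risk_times = seq(0, 18, by = risk_step))
    out <- reconstruct_ipd(dk)
    max(abs(survival_step_at(km_estimate(out, "os"), dk$curve$time) - dk$curve$survival))
  }
  # integer rounding leaves noise of order 1/n, so the comparison carries a
  # small slack; both densities must stay accurate in absolute terms
  e2 <- sup_err_at(2)
  e6 <- sup_err_at(6)
  expect_lte(e2, e6 + 0.002)
  expect_lt(e2, 0.02)
})

test_that("an increasing numbers-at-risk table is rejected", {
  expect_error(
    digitized_km(curve = data.frame(time = c(0, 1, 2), survival = c(1, 0.8, 0.6)),
                 risk_table = data.frame(time = c(0, 2), n_risk = c(10, 15))),
    class = "immunocea_validation_error")
})

test_that("a published event total steers the final-interval censoring", {
  # complete follow-up to the end of the digitized span, so the published
  # total refers to events the curve can actually carry
  cfg <- cohort_config(
    n = 200, arm = "regorafenib", seed = 23, cure_fraction = 0,
    latent_os = list(family = "loglogistic", params = c(scale = 8.8, shape = 1.7)),
    pfs = list(family = "loglogistic", params = c(scale = 3.2, shape = 1.9)),
    accrual_months = 0, followup_months = 15)
  dk <- generate_aggregate_trial(cfg, readoff_times = seq(0, 15, by = 0.5),
                                 risk_times = seq(0, 15, by = 3))
  with_total <- reconstruct_ipd(dk)
  dk_nototal <- dk
  dk_nototal$total_events <- NULL
  without_total <- reconstruct_ipd(dk_nototal)
  # the adjustment never moves away from the reported total, and any residual
  # mismatch (bounded by the final-interval censoring budget) stays small
  expect_lte(abs(sum(with_total$event) - dk$total_events),
             abs(sum(without_total$event) - dk$total_events))
  expect_lte(abs(sum(with_total$event) - dk$total_events), 0.05 * dk$total_events)
  # both modes still track the curve
  for (out in list(with_total, without_total)) {
    err <- max(abs(survival_step_at(km_estimate(out, "os"), dk$curve$time) - dk$curve$survival))
    expect_lt(err, 0.04)
  }
})
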