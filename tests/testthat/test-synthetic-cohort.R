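test_that("configuration validation rejects out-of-domain parameters", {
  expect_error(cohort_config(n = 10, cure_fraction = 1), class = "immunocea_config_error")
  expect_error(cohort_config(n = 10, cure_fraction = -0.1), class = "immunocea_config_error")
  expect_error(cohort_config(n = 0), class = "immunocea_config_error")
  expect_error(
    cohort_config(n = 10, latent_os = list(family = "weibull", params = c(shape = 1, scale = -2))),
    class = "immunocea_config_error")
  expect_error(
    cohort_config(n = 10, pfs = list(family = "nope", params = 1)),
    class = "immunocea_config_error")
})

test_that("no cure and unbounded follow-up yields a fully observed cohort", {
  cfg <- cohort_config(n = 3, seed = 4, cure_fraction = 0, accrual_months = 0,
                       followup_months = Inf)
  ipd <- generate_ipd(cfg)
  expect_equal(ipd$os_event, rep(1L, 3))
  expect_equal(ipd$pfs_event, rep(1L, 3))
})

test_that("generation is byte-identical for a fixed seed", {
  cfg <- intervention_cohort_config(seed = 99)
  expect_identical(generate_ipd(cfg), generate_ipd(cfg))
})

test_that("every generated record respects the domain invariants", {
  for (seed in c(1, 2, 3)) {
    ipd <- generate_ipd(intervention_cohort_config(seed = seed, n = 150))
    expect_true(all(ipd$pfs_time <= ipd$os_time + 1e-12))
    expect_true(all(is.finite(ipd$pfs_time) & ipd$pfs_time >= 0))
    expect_true(all(is.finite(ipd$os_time) & ipd$os_time >= 0))
    expect_true(all(ipd$sex %in% c("male", "female")))
    expect_true(all(ipd$ecog %in% c(0, 1)))
    expect_true(all(unlist(ipd[c("pfs_event", "os_event", "histology_adeno",
                                 "liver_met", "prior_lines_ge2", "prior_targeted")]) %in% 0:1))
    expect_true(all(ipd$age >= 18 & ipd$age <= 85))
  }
})

test_that("KM plateau height recovers the cure fraction at large n", {
  cfg <- cohort_config(n = 2000, seed = 21, cure_fraction = 0.4,
                       latent_os = list(family = "lognormal", params = c(meanlog = 2.2, sdlog = 0.7)),
                       accrual_months = 0, followup_months = 60)
  ipd <- generate_ipd(cfg)
  km <- km_estimate(ipd, "os")
  last_event <- max(km$time[km$n_event > 0])
  plateau <- survival_step_at(km, last_event)
  # binomial SE at the plateau is ~0.011; allow a generous MC band
  expect_lt(abs(plateau - 0.4), 0.05)
})

test_that("cumulative hazard is linear in time for exponential latent survival", {
  lambda <- 0.1
  cfg <- cohort_config(n = 5000, seed = 31, cure_fraction = 0,
                       latent_os = list(family = "exponential", params = c(rate = lambda)),
                       accrual_months = 0, followup_months = Inf)
  ipd <- generate_ipd(cfg)
  sf <- survival::survfit(survival::Surv(os_time, os_event) ~ 1, data = ipd)
  for (q in c(0.25, 0.5, 0.75)) {
    t_q <- unname(quantile(ipd$os_time, q))
    H <- sf$cumhaz[findInterval(t_q, sf$time)]
    expect_lt(abs(H / (lambda * t_q) - 1), 0.1)
  }
})

test_that("baseline summaries are exact proportions/means of the cohort", {
  ipd <- generate_ipd(intervention_cohort_config(seed = 5, n = 50))
  ipd$sex <- "male"
  s <- summarize_baseline(ipd)
  expect_equal(unname(s$covariate_means["sex_male"]), 1.0)
  expect_equal(s$n, 50)
  expect_error(summarize_baseline(ipd[0, ]), class = "immunocea_validation_error")

  big <- generate_ipd(cohort_config(n = 1000, seed = 6))
  prop <- summarize_baseline(big)$covariate_means["ecog1"]
  # exact binomial 99.9% envelope around the generating prevalence 0.5
  bounds <- qbinom(c(5e-4, 1 - 5e-4), 1000, 0.5) / 1000
  expect_gte(prop, bounds[1])
  expect_lte(prop, bounds[2])
})

test_that("aggregate read-outs behave like a published KM figure", {
  cfg <- comparator_cohort_config(seed = 8, n = 200)
  dk <- generate_aggregate_trial(cfg, readoff_times = seq(0, 15, by = 1.5))
  expect_equal(dk$curve$survival[dk$curve$time == 0], 1.0)
  expect_true(all(diff(dk$curve$survival) <= 0))
  expect_true(all(diff(dk$risk_table$n_risk) <= 0))
  expect_error(generate_aggregate_trial(cfg, readoff_times = c(0, 500)),
               class = "immunocea_validation_error")
})

test_that("subject-level CSV round-trips through the package readers", {
  ipd <- generate_ipd(intervention_cohort_config(seed = 3, n = 20))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ipd_csv(ipd, path)
  back <- read_ipd_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(ipd))
})
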