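test_that("targets at the sample means give uniform weights and full ESS", {
  ipd <- generate_ipd(intervention_cohort_config(seed = 51, n = 120))
  s <- summarize_baseline(ipd)
  fit <- fit_weights(ipd, s)
  expect_equal(fit$weights, rep(1, 120), tolerance = 1e-6)
  expect_equal(fit$ess, 120, tolerance = 1e-6)
  expect_equal(unname(fit$alpha), rep(0, length(fit$alpha)), tolerance = 1e-6)
})

test_that("a single binary covariate reproduces the closed-form two-level weights", {
  rec <- tibble::tibble(
    id = sprintf("A%03d", 1:100), arm = "serplulimab",
    age = 50, sex = "male", ecog = rep(c(1L, 0L), each = 50),
    histology_adeno = 1L, liver_met = 0L, prior_lines_ge2 = 0L, prior_targeted = 0L,
    pfs_time = 1, pfs_event = 1L, os_time = 2, os_event = 1L)
  fit <- fit_weights(rec, c(ecog1 = 0.6), covariates = "ecog1")
  expect_equal(unname(fit$achieved_means["ecog1"]), 0.6, tolerance = 1e-6)

  # closed-form oracle: ratio r solves 50 r / (50 r + 50) = 0.6 => r = 1.5;
  # rescaled to sum 100 the weights are 1.2 (x=1) and 0.8 (x=0)
  w1 <- 100 * 1.5 / (50 * 1.5 + 50)
  w0 <- 100 * 1.0 / (50 * 1.5 + 50)
  expect_equal(sort(unique(round(fit$weights, 8))), sort(c(w0, w1)), tolerance = 1e-6)
  ess_oracle <- sum(c(rep(w1, 50), rep(w0, 50)))^2 / sum(c(rep(w1, 50), rep(w0, 50))^2)
  expect_equal(fit$ess, ess_oracle, tolerance = 1e-6)
})

test_that("moment conditions hold to 1e-6 across all matched covariates", {
  ipd <- generate_ipd(intervention_cohort_config(seed = 52, n = 150))
  targets <- covariate_means_shifted(ipd, shift = 0.06)
  fit <- fit_weights(ipd, targets)
  expect_lt(max(abs(fit$achieved_means - fit$target_means)), 1e-6)
  expect_true(all(fit$weights >= 0))
  expect_lte(fit$ess, fit$n)
})

test_that("ESS decreases monotonically as the target moves from the sample mean", {
  ipd <- generate_ipd(intervention_cohort_config(seed = 53, n = 200))
  p0 <- mean(ipd$ecog == 1)
  grid <- p0 + c(0, 0.05, 0.1, 0.15, 0.2)
  ess <- vapply(grid, function(tgt) {
    fit_weights(ipd, c(ecog1 = tgt), covariates = "ecog1")$ess
  }, numeric(1))
  expect_true(all(diff(ess) < 0))
})

test_that("the solution is invariant to affine rescaling of continuous covariates", {
  ipd <- generate_ipd(intervention_cohort_config(seed = 54, n = 150))
  t_age <- mean(ipd$age) + 1.5
  fit1 <- fit_weights(ipd, c(age = t_age, ecog1 = 0.55), covariates = c("age", "ecog1"))
  scaled <- ipd
  scaled$age <- (ipd$age - 50) / 10
  fit2 <- fit_weights(scaled, c(age = (t_age - 50) / 10, ecog1 = 0.55),
                      covariates = c("age", "ecog1"))
  expect_equal(fit1$weights, fit2$weights, tolerance = 1e-8)
  expect_equal(unname(fit2$alpha["age"]), unname(fit1$alpha["age"]) * 10, tolerance = 1e-6)
})

test_that("infeasible or degenerate targets fail with informative errors", {
  ipd <- generate_ipd(intervention_cohort_config(seed = 55, n = 80))
  expect_error(fit_weights(ipd, c(ecog1 = 1.0), covariates = "ecog1"),
               class = "immunocea_validation_error")
  dup <- ipd
  dup$prior_targeted <- dup$ecog  # perfectly collinear with ecog1
  expect_error(
    fit_weights(dup, c(ecog1 = 0.55, prior_targeted = 0.55),
                covariates = c("ecog1", "prior_targeted")),
    regexp = "collinear")
})

test_that("weights propagate downstream and unmatched covariates float free", {
  ipd <- generate_ipd(intervention_cohort_config(seed = 56, n = 150))
  s <- summarize_baseline(ipd)
  null_fit <- fit_weights(ipd, s)
  w_ipd <- apply_weights(ipd, null_fit)
  expect_equal(km_estimate(w_ipd, "os")$survival, km_estimate(ipd, "os")$survival)

  targets <- covariate_means_shifted(ipd, shift = 0.08)
  partial <- fit_weights(ipd, targets, covariates = c("ecog1", "liver_met"))
  w <- partial$weights
  X <- cbind(sex_male = as.numeric(ipd$sex == "male"), ecog1 = as.numeric(ipd$ecog == 1),
             liver_met = as.numeric(ipd$liver_met))
  wm <- colSums(X * w) / sum(w)
  expect_equal(unname(wm["ecog1"]), unname(targets["ecog1"]), tolerance = 1e-6)
  expect_equal(unname(wm["liver_met"]), unname(targets["liver_met"]), tolerance = 1e-6)
  expect_gt(abs(wm["sex_male"] - targets["sex_male"]), 1e-4)
})

test_that("the weighted KM matches a cohort resampled proportionally to the weights", {
  ipd <- generate_ipd(intervention_cohort_config(seed = 57, n = 300))
  targets <- covariate_means_shifted(ipd, shift = 0.08)
  fit <- fit_weights(ipd, targets, covariates = c("ecog1", "liver_met"))
  km_w <- km_estimate(apply_weights(ipd, fit), "os")
  set.seed(58)
  idx <- sample.int(300, 40000, replace = TRUE, prob = fit$weights)
  km_rs <- km_estimate(ipd[idx, ], "os")
  grid <- seq(1, 30, by = 1)
  expect_lt(max(abs(survival_step_at(km_w, grid) - survival_step_at(km_rs, grid))), 0.02)
})
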