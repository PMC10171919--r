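test_that("degenerate bounds return the base ICER for every registry parameter", {
  run <- demo_run()
  reg <- param_registry(run$inputs)
  reg$low <- reg$base
  reg$high <- reg$base
  ow <- owsa(run, reg)
  expect_equal(ow$icer_low, rep(ow$icer_base[1], nrow(ow)))
  expect_equal(ow$icer_high, rep(ow$icer_base[1], nrow(ow)))
  expect_equal(max(ow$range), 0)
})

test_that("tornado rows separate cost-side from effect-side parameters", {
  run <- demo_run()
  reg <- param_registry(run$inputs)
  ow <- owsa(run, reg[reg$name %in% c("u_pd", "cost_regorafenib_hosp_pfs",
                                      "cost_serplulimab_drug_per_cycle",
                                      "discount_cost", "discount_qaly"), ])
  # a parameter whose base value is zero cannot move the ICER
  expect_equal(ow$range[ow$name == "cost_regorafenib_hosp_pfs"], 0)
  # u_pd moves incremental QALYs but not incremental cost
  base_ce <- immunocea:::rebuild_economics(run, run$inputs)
  lo_ce <- immunocea:::rebuild_economics(run, immunocea:::set_param(run$inputs, "u_pd", 0.8 * 0.57))
  expect_equal(lo_ce$delta_cost, base_ce$delta_cost, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(lo_ce$delta_qaly, base_ce$delta_qaly)))
  # discount rates are influential under the packaged base case
  expect_true(all(ow$range[ow$name %in% c("discount_cost", "discount_qaly")] > 0))
})

test_that("discount rates rank among the widest tornado bars on the packaged base case", {
  run <- demo_run()
  ow <- owsa(run)
  top10 <- head(ow$name, 10)
  expect_true(any(c("discount_cost", "discount_qaly") %in% top10))
})

test_that("beta moment matching is exact in the mean and rejects infeasible spreads", {
  h <- immunocea:::beta_hyper(0.84, 0.2 * 0.84)
  expect_equal(unname(h[1] / sum(h)), 0.84, tolerance = 1e-12)
  expect_error(immunocea:::beta_hyper(0.5, 0.6), class = "immunocea_config_error")
  set.seed(60)
  x <- rbeta(1000, h[1], h[2])
  expect_lt(abs(mean(x) - 0.84), 3 * 0.2 * 0.84 / sqrt(1000))
})

test_that("the PSA is bit-reproducible under a fixed seed", {
  run <- demo_run()
  d1 <- psa(run, n_draws = 25, seed = 77)
  d2 <- psa(run, n_draws = 25, seed = 77)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  d3 <- psa(run, n_draws = 25, seed = 78)
  expect_false(identical(d1$cost_ser, d3$cost_ser))
})

test_that("all-fixed registries make every PSA draw equal the base case", {
  run <- demo_run()
  reg <- param_registry(run$inputs)
  reg$dist <- "fixed"
  # also pin the survival blocks by zeroing their covariance
  run2 <- run
  for (nm in names(run2$fits)) {
    k <- length(run2$fits[[nm]]$best$theta)
    run2$fits[[nm]]$best$vcov <- matrix(0, k, k)
  }
  d <- psa(run2, n_draws = 5, seed = 5, registry = reg)
  base <- immunocea:::rebuild_economics(run, run$inputs)
  # the survival blocks keep a vanishing numerical jitter from the Cholesky
  # regularization, so agreement is to ~1e-4 relative, not bit-exact
  expect_equal(d$cost_ser, rep(base$arms$cost[1], 5), tolerance = 1e-4)
  expect_equal(d$qaly_ser, rep(base$arms$qaly[1], 5), tolerance = 1e-4)
  expect_equal(d$cost_reg, rep(base$arms$cost[2], 5), tolerance = 1e-4)
})

test_that("acceptability curves are proper, exact exceedance fractions", {
  run <- demo_run()
  d <- psa(run, n_draws = 60, seed = 41)
  grid <- seq(0, 60000, by = 5000)
  cc <- ceac(d, grid)
  expect_true(all(cc$prob_cost_effective >= 0 & cc$prob_cost_effective <= 1))
  for (i in c(1, 5, 13)) {
    count <- sum(grid[i] * d$delta_qaly - d$delta_cost > 0)
    expect_equal(cc$prob_cost_effective[i], count / 60)
  }
  if (all(d$delta_qaly > 0)) {
    expect_true(all(diff(cc$prob_cost_effective) >= 0))
  }
  # drawn cure fraction and QALY gain move together
  expect_gt(cor(d$cure_fraction_ser, d$delta_qaly, method = "spearman"), 0)
})

test_that("scenario overrides behave as documented", {
  run <- demo_run()
  expect_error(run_scenario("bogus", run), class = "immunocea_config_error")

  s4a <- run_scenario("utilities_astrum", run)
  expect_equal(s4a$arm_results$cost, run$arm_results$cost, tolerance = 1e-12)
  expect_equal(s4a$arm_results$ly, run$arm_results$ly, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(s4a$arm_results$qaly, run$arm_results$qaly)))
  s4b <- run_scenario("utilities_correct", run)
  expect_lt(s4b$arm_results$qaly[1], run$arm_results$qaly[1])

  s2 <- run_scenario("horizon_36m", run)
  expect_true(all(s2$arm_results$qaly <= run$arm_results$qaly + 1e-12))
  expect_true(all(s2$arm_results$ly <= run$arm_results$ly + 1e-12))

  s3 <- run_scenario("death_risk_4x", run)
  expect_true(all(s3$arm_results$ly <= run$arm_results$ly + 1e-12))

  s1 <- suppressWarnings(run_scenario("no_maic", run))
  expect_equal(s1$arm_results$cost[2], run$arm_results$cost[2], tolerance = 1e-9)
})
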