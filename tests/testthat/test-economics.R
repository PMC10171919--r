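inputs <- load_econ_inputs()

test_that("drug dosing rules reproduce the per-cycle acquisition costs", {
  # 3 mg/kg x 65 kg = 195 mg -> 2 whole 100 mg vials, twice per cycle
  expect_equal(drug_cost_per_cycle("serplulimab", 0, inputs), 2 * 828.92 * 2)
  expect_equal(drug_cost_per_cycle("serplulimab", 25, inputs), 3315.68)
  expect_equal(drug_cost_per_cycle("serplulimab", 26, inputs), 0)  # 2-year cap
  expect_equal(drug_cost_per_cycle("regorafenib", 0, inputs), 21 * 102.34)
  expect_equal(drug_cost_per_cycle("regorafenib", 100, inputs), 21 * 102.34)
  expect_error(drug_cost_per_cycle("serplulimab", -1, inputs),
               class = "immunocea_config_error")
})

test_that("incidence-to-cycle probability conversion inverts correctly", {
  expect_equal(rate_convert(0, 12), 0)
  # horizon equal to one cycle returns the incidence unchanged
  cycle_months <- 28 / (365.25 / 12)
  expect_equal(rate_convert(0.3, cycle_months), 0.3, tolerance = 1e-12)
  # compounding the per-cycle probability over the horizon re-yields the incidence
  p <- rate_convert(0.027, 12)
  n_cycles <- 12 / cycle_months
  expect_equal(1 - (1 - p)^n_cycles, 0.027, tolerance = 1e-10)
})

test_that("a death-only trace accrues exactly the end-of-life cost", {
  tr <- run_cohort(toy_schedule(p_death = 1, p_prog = 0), horizon = "fixed", n_cycles = 1)
  zi <- zero_cost_inputs(inputs)
  zi$costs$serplulimab[["eol"]] <- 2046.84
  zi$ae <- zi$ae[0, ]
  cc <- cycle_costs(tr, zi, "serplulimab")
  expect_equal(sum(cc$total), 2046.84)
})

test_that("per-cycle costs are constant within a monitoring band for a static cohort", {
  tr <- run_cohort(toy_schedule(p_death = rep(0, 60), p_prog = rep(0, 60)),
                   horizon = "fixed", n_cycles = 60)
  cc <- cycle_costs(tr, inputs, "regorafenib")
  in_band <- cc$t_years > 0 & cc$t_years < 3
  expect_equal(length(unique(round(cc$total[in_band], 9))), 1)
  # regorafenib accrues no administration cost while progression-free
  expect_equal(cc$administration, rep(0, nrow(cc)))
})

test_that("a three-cycle toy model matches an independent spreadsheet-style oracle", {
  p_death <- c(0.05, 0.10, 0.15)
  p_prog <- c(0.20, 0.15, 0.10)
  tr <- run_cohort(toy_schedule(p_death, p_prog), horizon = "fixed", n_cycles = 3)
  cc <- cycle_costs(tr, inputs, "serplulimab")
  eff <- qaly_accumulate(tr, inputs, "serplulimab", discount_rate = 0)

  # --- oracle: literal cell-by-cell arithmetic, independent of the package ---
  occ_pfs <- c(1, 0.75, 0.75 * 0.75, 0.75 * 0.75 * 0.75)
  alive <- c(1, 0.95, 0.95 * 0.90, 0.95 * 0.90 * 0.85)
  occ_pd <- alive - occ_pfs
  deaths <- c(0.05, 0.95 * 0.10, 0.95 * 0.90 * 0.15)
  expect_equal(tr$occ_pfs, occ_pfs, tolerance = 1e-12)
  expect_equal(tr$occ_pd, occ_pd, tolerance = 1e-12)

  ae <- inputs$ae[inputs$ae$arm == "serplulimab", ]
  oneoff <- ae[ae$kind == "one_off", ]
  hyper <- ae[ae$kind == "periodic", ]
  r_month <- -log(1 - hyper$incidence) / 9.83
  p_hyper <- 1 - exp(-r_month * 28 / 30.4375)

  cost_cells <- numeric(3)
  for (j in 1:3) {
    pf <- occ_pfs[j]; pd <- occ_pd[j]
    cell <- pf * 3315.68 +                         # drug (all cycles < 26)
      pf * 75.65 + pd * 75.65 +                    # monitoring, first band / PD
      pf * 2.97 + pd * 1.67 +                      # administration
      pf * 73.38 + pd * 110.08 +                   # hospitalization
      pd * 749.71 +                                # subsequent treatment
      pf * p_hyper * 0.18 +                        # periodic AE management
      deaths[j] * 2046.84                          # end-of-life
    if (j == 1) cell <- cell + 519.26 + sum(oneoff$incidence * oneoff$mgmt_cost)
    cost_cells[j] <- cell
  }
  expect_equal(round(cc$total, 2), round(cost_cells, 2))
  expect_equal(sum(cc$total), sum(cost_cells), tolerance = 1e-9)

  cyc_yr <- 28 / 365.25
  ly_oracle <- sum(alive[1:3]) * cyc_yr
  qaly_oracle <- sum(occ_pfs[1:3] * 0.84 + occ_pd[1:3] * 0.57) * cyc_yr -
    sum(oneoff$incidence * oneoff$disutility) * cyc_yr -
    sum(occ_pfs[1:3]) * p_hyper * 0.04 * cyc_yr
  expect_equal(eff$ly, ly_oracle, tolerance = 1e-9)
  expect_equal(eff$qaly, qaly_oracle, tolerance = 1e-9)
})

test_that("cost streams decompose additively and scale linearly", {
  run <- demo_run()
  cc <- cycle_costs(run$ser$trace, inputs, "serplulimab")
  comp <- rowSums(cc[, c("drug", "diagnosis", "monitoring", "administration",
                         "hospitalization", "subsequent", "ae_one_off",
                         "ae_periodic", "end_of_life")])
  expect_equal(comp, cc$total, tolerance = 1e-9)

  doubled <- inputs
  for (arm in names(doubled$costs)) doubled$costs[[arm]] <- doubled$costs[[arm]] * 2
  doubled$ae$mgmt_cost <- doubled$ae$mgmt_cost * 2
  ce1 <- compute_icer(arm_result(run$ser$trace, inputs, "serplulimab"),
                      arm_result(run$reg$trace, inputs, "regorafenib"))
  ce2 <- compute_icer(arm_result(run$ser$trace, doubled, "serplulimab"),
                      arm_result(run$reg$trace, doubled, "regorafenib"))
  expect_equal(ce2$delta_cost, 2 * ce1$delta_cost, tolerance = 1e-9)
  expect_equal(ce2$delta_qaly, ce1$delta_qaly, tolerance = 1e-12)
})

test_that("discounting is monotone in the rate and inactive at r = 0", {
  run <- demo_run()
  tr <- run$ser$trace
  rates <- c(0, 0.02, 0.05, 0.08, 0.1)
  totals <- vapply(rates, function(r) {
    i2 <- inputs; i2$discount_cost <- r; i2$discount_qaly <- r
    res <- arm_result(tr, i2, "serplulimab")
    c(res$cost, res$qaly)
  }, numeric(2))
  expect_true(all(diff(totals[1, ]) < 0))
  expect_true(all(diff(totals[2, ]) < 0))
  i0 <- inputs; i0$discount_cost <- 0; i0$discount_qaly <- 0
  res0 <- arm_result(tr, i0, "serplulimab")
  expect_equal(res0$cost, res0$cost_undisc)
  expect_equal(res0$qaly, res0$qaly_undisc)

  # unit utilities and no adverse events make QALY equal LY
  iu <- inputs; iu$u_pfs <- 1; iu$u_pd <- 1; iu$ae <- iu$ae[0, ]
  eff <- qaly_accumulate(tr, iu, "serplulimab", discount_rate = 0)
  expect_equal(eff$qaly, eff$ly, tolerance = 1e-12)
})

test_that("single-cycle QALY arithmetic and the discount factor are exact", {
  tr <- run_cohort(toy_schedule(p_death = 1, p_prog = 0), horizon = "fixed", n_cycles = 1)
  iu <- inputs; iu$ae <- iu$ae[0, ]
  eff <- qaly_accumulate(tr, iu, "serplulimab", discount_rate = 0)
  expect_equal(eff$qaly, 0.84 * 28 / 365.25, tolerance = 1e-12)
  expect_equal(immunocea:::discount_factor(1, 0.05), 1 / 1.05)
})

test_that("the ICER handles deltas, dominance and undefined cases", {
  mk_arm <- function(cost, qaly) tibble::tibble(arm = "x", cost = cost,
                                                cost_undisc = cost, ly = qaly,
                                                qaly = qaly, ly_undisc = qaly,
                                                qaly_undisc = qaly)
  ce <- compute_icer(mk_arm(65966.84, 4.98), mk_arm(40037.52, 0.69))
  expect_equal(ce$delta_cost, 25929.32, tolerance = 1e-9)
  expect_equal(ce$delta_qaly, 4.29, tolerance = 1e-12)
  expect_equal(ce$icer, 25929.32 / 4.29, tolerance = 1e-9)

  same <- compute_icer(mk_arm(10, 1), mk_arm(10, 1))
  expect_equal(same$dominance, "undefined")
  expect_true(is.na(same$icer))
  dom <- compute_icer(mk_arm(5, 2), mk_arm(10, 1))
  expect_equal(dom$dominance, "dominant")
  expect_true(dom$cost_effective)
})
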