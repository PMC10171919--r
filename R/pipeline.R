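# End-to-end orchestration: synthesize or load evidence, reconstruct the
# comparator pseudo-IPD, reweight the intervention arm, fit and extrapolate
# survival, floor against background mortality, run the cohort model, and
# attach the cost/utility layer.

#' Top-level analysis configuration
#'
#' One object holding every switch of the base-case analysis. All randomness
#' descends from `seed` (sub-seeds are derived deterministically and logged).
#'
#' @param seed master integer seed.
#' @param intervention,comparator [cohort_config()]s for the two arms (their
#'   `seed` fields are overridden from `seed`).
#' @param use_maic reweight the intervention arm to the comparator moments?
#' @param maic_covariates covariates entering the matching.
#' @param start_age,prop_male cohort age (years) and proportion male at model
#'   start (required configuration; the source analysis does not publish
#'   them).
#' @param k background-mortality multiplier (2 base case, 4 in scenario).
#' @param horizon `"lifetime"` or `"fixed"`.
#' @param n_cycles_fixed cycle count for the fixed horizon (39 cycles = the
#'   largest whole number of 28-day cycles inside 36 months).
#' @param n_cycles_max extrapolation grid length in cycles.
#' @param families base-case family choices per curve (`ser_pfs`, `ser_os`,
#'   `reg_pfs`, `reg_os`); `"cure_lognormal"` selects the mixture cure model.
#' @param readoff_step,risk_step spacing (months) of the simulated digitized
#'   curve and its risk table.
#' @param utility_set,discount_cost,discount_qaly,wtp passed to
#'   [load_econ_inputs()].
#' @param inputs_dir directory of the economic fixture CSVs.
#' @param life_table_path life table CSV path.
#' @return a `cea_config` list.
#' @export
cea_config <- function(seed = 1,
                       intervention = intervention_cohort_config(),
                       comparator = comparator_cohort_config(),
                       use_maic = TRUE,
                       maic_covariates = subject_covariate_names(),
                       start_age = 55, prop_male = 0.55,
                       k = 2,
                       horizon = c("lifetime", "fixed"),
                       n_cycles_fixed = 39,
                       n_cycles_max = 780,
                       families = list(ser_pfs = "gompertz",
                                       ser_os = "cure_lognormal",
                                       reg_pfs = "loglogistic",
                                       reg_os = "loglogistic"),
                       readoff_step = 0.5, risk_step = 2,
                       utility_set = "base",
                       discount_cost = 0.05, discount_qaly = 0.05,
                       wtp = 36036,
                       inputs_dir = system.file("extdata", package = "immunocea"),
                       life_table_path = system.file("extdata", "life_table_synthetic.csv",
                                                     package = "immunocea")) {
  horizon <- arg_match(horizon)
  if (k < 1) abort_config("`k` must be >= 1")
  seed <- as.integer(seed)
  intervention$seed <- seed
  comparator$seed <- seed + 1000L
  structure(list(
    seed = seed, intervention = intervention, comparator = comparator,
    use_maic = use_maic, maic_covariates = maic_covariates,
    start_age = start_age, prop_male = prop_male, k = k,
    horizon = horizon, n_cycles_fixed = n_cycles_fixed,
    n_cycles_max = n_cycles_max, families = families,
    readoff_step = readoff_step, risk_step = risk_step,
    utility_set = utility_set, discount_cost = discount_cost,
    discount_qaly = discount_qaly, wtp = wtp,
    inputs_dir = inputs_dir, life_table_path = life_table_path
  ), class = "cea_config")
}

digitize_from_cohort <- function(cohort, endpoint, readoff_step, risk_step) {
  time <- cohort[[paste0(endpoint, "_time")]]
  t_max <- max(time)
  readoff <- seq(0, t_max, by = readoff_step)
  risk <- seq(0, t_max, by = risk_step)
  km <- km_estimate(cohort, endpoint = endpoint)
  obs_time <- time
  n_at_risk <- vapply(risk, function(t) sum(obs_time >= t), numeric(1))
  digitized_km(
    curve = tibble(time = readoff, survival = survival_step_at(km, readoff)),
    risk_table = tibble(time = risk, n_risk = n_at_risk),
    total_events = sum(cohort[[paste0(endpoint, "_event")]])
  )
}

fit_curve <- function(cohort, endpoint, choice) {
  fits <- lapply(setNames(SURV_FAMILIES, SURV_FAMILIES), function(fam) {
    fit_parametric(cohort, endpoint = endpoint, family = fam)
  })
  if (startsWith(choice, "cure_")) {
    latent <- sub("^cure_", "", choice)
    fits[[choice]] <- suppressWarnings(
      fit_mixture_cure(cohort, endpoint = endpoint, latent_family = latent))
  }
  select_best(fits, override = choice)
}

extrapolate_arm <- function(fit_pfs, fit_os, life_table, config) {
  s_pfs <- apply_mortality_floor(fit_pfs, life_table, config$start_age,
                                 config$prop_male, k = config$k,
                                 n_cycles = config$n_cycles_max)
  s_os <- apply_mortality_floor(fit_os, life_table, config$start_age,
                                config$prop_male, k = config$k,
                                n_cycles = config$n_cycles_max)
  ts <- derive_transitions(s_pfs, s_os)
  trace <- run_cohort(ts, horizon = config$horizon,
                      n_cycles = config$n_cycles_fixed)
  list(s_pfs = s_pfs, s_os = s_os, schedule = ts, trace = trace)
}

#' Run the full cost-effectiveness pipeline
#'
#' Stages, in order: synthesize the intervention IPD and the comparator's
#' aggregate read-out; reconstruct comparator pseudo-IPD from the digitized
#' curves; reweight the intervention arm to the comparator's baseline moments
#' (unless disabled); fit the candidate survival models per curve and apply
#' the configured base-case choices; floor against k-fold general-population
#' mortality on the 28-day grid; derive transitions and run the cohort model;
#' attach costs and utilities and compute the ICER.
#'
#' @param config a [cea_config()].
#' @return a `cea_run` bundle: the inputs, every intermediate (digitized
#'   curves, reconstructed cohorts, MAIC fit, survival fits with rankings,
#'   floored curves, schedules, traces), the per-arm results, the `ce_result`,
#'   and a log of seeds and repair/clamping diagnostics.
#' @export
#' @examples
#' \donttest{
#' run <- run_pipeline(cea_config(seed = 1))
#' glance(run$ce)
#' }
run_pipeline <- function(config = cea_config()) {
  stopifnot(inherits(config, "cea_config"))
  stage <- function(name, code) {
    tryCatch(force(code), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "immunocea_stage_error")
    })
  }

  inputs <- stage("load_inputs", load_econ_inputs(
    dir = config$inputs_dir, utility_set = config$utility_set,
    discount_cost = config$discount_cost, discount_qaly = config$discount_qaly,
    wtp = config$wtp))
  life_table <- stage("load_life_table", read_life_table(config$life_table_path))

  ipd <- stage("synthesize_intervention", generate_ipd(config$intervention))
  hidden <- stage("synthesize_comparator", generate_ipd(config$comparator))
  dk_os <- stage("digitize_os", digitize_from_cohort(
    hidden, "os", config$readoff_step, config$risk_step))
  dk_pfs <- stage("digitize_pfs", digitize_from_cohort(
    hidden, "pfs", config$readoff_step, config$risk_step))

  recon_os <- stage("reconstruct_os", reconstruct_ipd(dk_os))
  recon_pfs <- stage("reconstruct_pfs", reconstruct_ipd(dk_pfs))

  maic <- NULL
  weighted <- ipd
  if (config$use_maic) {
    targets <- structure(list(
      n = config$comparator$n,
      covariate_means = covariate_expectations(config$comparator$covariate_prevalences)
    ), class = "trial_summary")
    maic <- stage("maic", fit_weights(ipd, targets,
                                      covariates = config$maic_covariates))
    weighted <- apply_weights(ipd, maic)
  }

  sel_ser_pfs <- stage("fit_ser_pfs", fit_curve(weighted, "pfs", config$families$ser_pfs))
  sel_ser_os <- stage("fit_ser_os", fit_curve(weighted, "os", config$families$ser_os))
  sel_reg_pfs <- stage("fit_reg_pfs", fit_curve(recon_pfs, "pfs", config$families$reg_pfs))
  sel_reg_os <- stage("fit_reg_os", fit_curve(recon_os, "os", config$families$reg_os))

  ser <- stage("extrapolate_ser", extrapolate_arm(
    sel_ser_pfs$best, sel_ser_os$best, life_table, config))
  reg <- stage("extrapolate_reg", extrapolate_arm(
    sel_reg_pfs$best, sel_reg_os$best, life_table, config))

  res_ser <- stage("economics_ser", arm_result(ser$trace, inputs, "serplulimab"))
  res_reg <- stage("economics_reg", arm_result(reg$trace, inputs, "regorafenib"))
  ce <- stage("icer", compute_icer(res_ser, res_reg, wtp = inputs$wtp))

  log <- list(
    seeds = c(master = config$seed,
              intervention = config$intervention$seed,
              comparator = config$comparator$seed),
    maic = if (!is.null(maic)) glance(maic) else NULL,
    km_repairs = c(os = attr(dk_os, "repairs"), pfs = attr(dk_pfs, "repairs")),
    transition_diagnostics = list(
      serplulimab = attr(ser$schedule, "diagnostics"),
      regorafenib = attr(reg$schedule, "diagnostics")),
    convergence = c(ser_pfs = sel_ser_pfs$best$converged,
                    ser_os = sel_ser_os$best$converged,
                    reg_pfs = sel_reg_pfs$best$converged,
                    reg_os = sel_reg_os$best$converged)
  )

  structure(list(
    config = config, inputs = inputs, life_table = life_table,
    ipd = ipd, weighted = weighted, maic = maic,
    dk_os = dk_os, dk_pfs = dk_pfs,
    recon_os = recon_os, recon_pfs = recon_pfs,
    fits = list(ser_pfs = sel_ser_pfs, ser_os = sel_ser_os,
                reg_pfs = sel_reg_pfs, reg_os = sel_reg_os),
    ser = ser, reg = reg,
    arm_results = bind_rows(res_ser, res_reg),
    ce = ce, log = log
  ), class = "cea_run")
}

#' @export
#' @exportS3Method
print.cea_run <- function(x, ...) {
  cat(sprintf("<cea_run> seed %d, %s horizon, k = %g, MAIC %s\n",
              x$config$seed, x$config$horizon, x$config$k,
              if (x$config$use_maic) "on" else "off"))
  print(x$ce)
  invisible(x)
}

#' @export
#' @exportS3Method
glance.cea_run <- function(x, ...) glance(x$ce)

#' Validate analysis input files
#'
#' Schema and domain checks on every CSV a configuration points at: cost
#' table completeness and nonnegativity, adverse-event incidence domains,
#' utility ranges, life-table monotone ages and closed terminal row. Returns
#' one row per check; `fatal` distinguishes errors from warnings.
#'
#' @param config a [cea_config()].
#' @return tibble with columns `check`, `ok`, `fatal`, `message`.
#' @export
validate_inputs <- function(config = cea_config()) {
  checks <- list()
  add <- function(check, ok, fatal, message = "") {
    checks[[length(checks) + 1]] <<- tibble(check = check, ok = ok,
                                            fatal = fatal, message = message)
  }
  try_read <- function(name, expr) {
    tryCatch({ v <- force(expr); add(name, TRUE, TRUE); v },
             error = function(e) { add(name, FALSE, TRUE, conditionMessage(e)); NULL })
  }
  inputs <- try_read("economic_inputs_parse", load_econ_inputs(
    dir = config$inputs_dir, utility_set = config$utility_set))
  if (!is.null(inputs)) {
    add("costs_nonnegative", all(unlist(inputs$costs) >= 0), TRUE)
    add("ae_incidences_in_unit_interval",
        all(inputs$ae$incidence >= 0 & inputs$ae$incidence <= 1), TRUE)
    add("utilities_in_unit_interval",
        inputs$u_pfs >= 0 && inputs$u_pfs <= 1 && inputs$u_pd >= 0 && inputs$u_pd <= 1,
        TRUE)
    add("periodic_ae_present", any(inputs$ae$kind == "periodic"), FALSE,
        "no periodic adverse events configured")
  }
  lt <- try_read("life_table_parse", read_life_table(config$life_table_path))
  if (!is.null(lt)) {
    add("life_table_start_age_covered",
        config$start_age >= min(lt$age) && config$start_age <= max(lt$age), TRUE)
  }
  bind_rows(checks)
}

#' Export the main artifacts of a run as CSV files
#'
#' Writes the intervention IPD, reconstructed comparator cohorts, MAIC
#' weights, per-cycle traces and the results table into a directory, each
#' re-loadable by the package's own readers.
#'
#' @param run a `cea_run`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
export_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_ipd_csv(run$ipd, file.path(dir, "intervention_ipd.csv"))
  readr::write_csv(run$recon_os, file.path(dir, "comparator_recon_os.csv"))
  readr::write_csv(run$recon_pfs, file.path(dir, "comparator_recon_pfs.csv"))
  if (!is.null(run$maic)) {
    readr::write_csv(tibble(id = run$ipd$id, weight = run$maic$weights),
                     file.path(dir, "maic_weights.csv"))
  }
  readr::write_csv(as_tibble(run$ser$trace), file.path(dir, "trace_serplulimab.csv"))
  readr::write_csv(as_tibble(run$reg$trace), file.path(dir, "trace_regorafenib.csv"))
  readr::write_csv(run$arm_results, file.path(dir, "arm_results.csv"))
  readr::write_csv(glance(run$ce), file.path(dir, "icer.csv"))
  rankings <- imap(run$fits, function(s, nm) mutate(s$ranking, curve = nm)) |> list_rbind()
  readr::write_csv(rankings, file.path(dir, "fit_rankings.csv"))
  invisible(dir)
}
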