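# Seeded synthetic trial-data generator. Emulates the statistical structure the
# downstream analysis assumes: a cured/uncured mixture for overall survival in
# the immunotherapy arm (long-term survivor plateau), a single-population
# comparator, PFS coupled below OS, and administrative censoring from uniform
# accrual plus a fixed follow-up window.

run_with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles the data-generating parameters for one trial arm: a cure/no-cure
#' mixture for latent overall survival, a single-population PFS distribution
#' truncated at OS, baseline covariate prevalences, and an accrual +
#' fixed-follow-up censoring mechanism.
#'
#' @param n number of subjects.
#' @param arm arm label, `"serplulimab"` or `"regorafenib"`.
#' @param seed integer seed; generation is byte-reproducible for a fixed seed.
#' @param cure_fraction probability in `[0, 1)` of belonging to the cured
#'   (long-term survivor) component.
#' @param latent_os list `(family, params)` for uncured latent OS (months).
#' @param pfs list `(family, params)` for latent PFS (months).
#' @param covariate_prevalences named list of baseline covariate parameters:
#'   `age_mean`, `age_sd`, and prevalences for `sex_male`, `ecog1`,
#'   `histology_adeno`, `liver_met`, `prior_lines_ge2`, `prior_targeted`.
#' @param covariate_effects list with optional named vectors `cure` (log-odds
#'   shifts on the cure probability) and `os` (log-time AFT shifts on latent
#'   OS), keyed by covariate name; covariates are centred at their expected
#'   values so the marginal `cure_fraction` is preserved.
#' @param accrual_months uniform accrual window (months).
#' @param followup_months minimum administrative follow-up after the last
#'   accrued subject; may be `Inf` for complete follow-up.
#' @param long_pfs_prob probability that a cured subject also has durable PFS
#'   (reproduces the plateau seen in both endpoints).
#' @param dropout_rate optional exponential dropout rate per month (0 = none).
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n,
                          arm = c("serplulimab", "regorafenib"),
                          seed = NULL,
                          cure_fraction = 0,
                          latent_os = list(family = "lognormal", params = c(meanlog = 2.2, sdlog = 0.8)),
                          pfs = list(family = "weibull", params = c(shape = 1.2, scale = 13.3)),
                          covariate_prevalences = default_prevalences(),
                          covariate_effects = list(),
                          accrual_months = 12,
                          followup_months = 36,
                          long_pfs_prob = 0.7,
                          dropout_rate = 0) {
  arm <- arg_match(arm)
  if (!is.numeric(n) || length(n) != 1 || n < 1) abort_config("`n` must be a positive count")
  check_probability(cure_fraction, "cure_fraction", allow_one = FALSE)
  check_probability(long_pfs_prob, "long_pfs_prob")
  check_nonnegative(dropout_rate, "dropout_rate")
  check_nonnegative(accrual_months, "accrual_months")
  if (followup_months <= 0) abort_config("`followup_months` must be positive")
  for (d in list(latent_os, pfs)) {
    if (!d$family %in% SURV_FAMILIES) abort_config(sprintf("unknown family '%s'", d$family))
    pos <- d$params[surv_log_scale(d$family)]
    if (any(pos <= 0)) abort_config("scale/rate/shape parameters must be positive")
  }
  prev <- covariate_prevalences
  for (nm in setdiff(names(prev), c("age_mean", "age_sd"))) {
    check_probability(prev[[nm]], nm)
  }
  structure(
    list(n = as.integer(n), arm = arm, seed = seed, cure_fraction = cure_fraction,
         latent_os = latent_os, pfs = pfs,
         covariate_prevalences = prev, covariate_effects = covariate_effects,
         accrual_months = accrual_months, followup_months = followup_months,
         long_pfs_prob = long_pfs_prob, dropout_rate = dropout_rate),
    class = "cohort_config")
}

default_prevalences <- function() {
  list(age_mean = 55, age_sd = 10, sex_male = 0.55, ecog1 = 0.5,
       histology_adeno = 0.9, liver_met = 0.4, prior_lines_ge2 = 0.6,
       prior_targeted = 0.5)
}

#' Packaged intervention-arm generating configuration
#'
#' Defaults emulate a single-arm anti-PD-1 trial in previously treated
#' MSI-H/dMMR colorectal cancer: 74 subjects, a 0.55 cure fraction producing
#' the immature L-shaped OS plateau, latent log-normal OS for the uncured,
#' PFS with median near 9.8 months, 12 months of accrual and a 36-month
#' follow-up window.
#'
#' @param seed integer seed.
#' @param n number of subjects.
#' @return a [cohort_config()].
#' @export
intervention_cohort_config <- function(seed = NULL, n = 74) {
  cohort_config(
    n = n, arm = "serplulimab", seed = seed,
    cure_fraction = 0.55,
    latent_os = list(family = "lognormal", params = c(meanlog = 2.35, sdlog = 0.75)),
    pfs = list(family = "weibull", params = c(shape = 1.2, scale = 13.3)),
    covariate_effects = list(
      cure = c(ecog1 = -0.5, liver_met = -0.4),
      os = c(ecog1 = -0.25, liver_met = -0.2, prior_lines_ge2 = -0.1)
    ),
    accrual_months = 12, followup_months = 36, long_pfs_prob = 0.7)
}

#' Packaged comparator-arm generating configuration
#'
#' Emulates the regorafenib evidence consumed as aggregate data: 136 subjects,
#' no cured component, log-logistic OS with median 8.8 months and log-logistic
#' PFS with median 3.2 months (the comparator trial's published medians used
#' as calibration inputs), slightly older and more male population.
#'
#' @param seed integer seed.
#' @param n number of subjects.
#' @return a [cohort_config()].
#' @export
comparator_cohort_config <- function(seed = NULL, n = 136) {
  prev <- default_prevalences()
  prev$age_mean <- 57
  prev$sex_male <- 0.62
  prev$ecog1 <- 0.6
  prev$liver_met <- 0.5
  prev$prior_lines_ge2 <- 0.7
  prev$prior_targeted <- 0.4
  cohort_config(
    n = n, arm = "regorafenib", seed = seed,
    cure_fraction = 0,
    latent_os = list(family = "loglogistic", params = c(scale = 8.8, shape = 1.7)),
    pfs = list(family = "loglogistic", params = c(scale = 3.2, shape = 1.9)),
    covariate_prevalences = prev,
    accrual_months = 12, followup_months = 24)
}

subject_covariate_names <- function() {
  c("age", "sex_male", "ecog1", "histology_adeno", "liver_met",
    "prior_lines_ge2", "prior_targeted")
}

# expected value of each covariate under the config prevalences (for centring)
covariate_expectations <- function(prev) {
  c(age = prev$age_mean, sex_male = prev$sex_male, ecog1 = prev$ecog1,
    histology_adeno = prev$histology_adeno, liver_met = prev$liver_met,
    prior_lines_ge2 = prev$prior_lines_ge2, prior_targeted = prev$prior_targeted)
}

#' Generate synthetic individual patient data
#'
#' Draws one subject-level cohort under a [cohort_config()]. Cured subjects
#' (Bernoulli with logistic covariate shifts) receive infinite latent OS
#' before censoring; uncured subjects draw OS from the latent distribution
#' with accelerated-failure-time covariate shifts. PFS is drawn conditionally
#' below OS (resampling, truncating at OS on exhaustion). Censoring combines
#' uniform accrual, a fixed administrative follow-up window and optional
#' exponential dropout.
#'
#' @param config a [cohort_config()].
#' @return a tibble with one row per subject: `id`, `arm`, covariates
#'   (`age`, `sex`, `ecog`, `histology_adeno`, `liver_met`, `prior_lines_ge2`,
#'   `prior_targeted`), and `pfs_time`, `pfs_event`, `os_time`, `os_event`
#'   (months, event flags). Satisfies `pfs_time <= os_time` row-wise.
#' @export
#' @examples
#' ipd <- generate_ipd(intervention_cohort_config(seed = 1, n = 20))
generate_ipd <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  run_with_seed(config$seed, {
    n <- config$n
    prev <- config$covariate_prevalences
    age <- pmin(pmax(rnorm(n, prev$age_mean, prev$age_sd), 18), 85)
    covs <- tibble(
      age = age,
      sex_male = rbinom(n, 1, prev$sex_male),
      ecog1 = rbinom(n, 1, prev$ecog1),
      histology_adeno = rbinom(n, 1, prev$histology_adeno),
      liver_met = rbinom(n, 1, prev$liver_met),
      prior_lines_ge2 = rbinom(n, 1, prev$prior_lines_ge2),
      prior_targeted = rbinom(n, 1, prev$prior_targeted)
    )
    ex <- covariate_expectations(prev)
    centred <- sweep(as.matrix(covs), 2, ex[colnames(covs)])

    lin_shift <- function(beta) {
      if (length(beta) == 0) return(rep(0, n))
      beta <- beta[names(beta) %in% colnames(centred)]
      if (length(beta) == 0) return(rep(0, n))
      drop(centred[, names(beta), drop = FALSE] %*% beta)
    }

    cf <- config$cure_fraction
    cured <- if (cf > 0) {
      lp <- qlogis(cf) + lin_shift(config$covariate_effects$cure)
      rbinom(n, 1, plogis(lp)) == 1
    } else rep(FALSE, n)

    os_latent <- rsurv_parametric(n, config$latent_os$family, config$latent_os$params) *
      exp(lin_shift(config$covariate_effects$os))
    os_latent[cured] <- Inf

    pfs_latent <- rsurv_parametric(n, config$pfs$family, config$pfs$params)
    # resample PFS above OS; truncate at OS after 100 rounds
    for (i in 1:100) {
      bad <- which(pfs_latent > os_latent)
      if (length(bad) == 0) break
      pfs_latent[bad] <- rsurv_parametric(length(bad), config$pfs$family, config$pfs$params)
    }
    pfs_latent <- pmin(pfs_latent, os_latent)
    if (any(cured)) {
      durable <- cured & (runif(n) < config$long_pfs_prob)
      pfs_latent[durable] <- Inf
    }

    entry <- runif(n, 0, config$accrual_months)
    censor <- config$accrual_months + config$followup_months - entry
    if (config$dropout_rate > 0) {
      censor <- pmin(censor, stats::rexp(n, config$dropout_rate))
    }

    out <- bind_cols(
      tibble(id = sprintf("%s%04d", toupper(substr(config$arm, 1, 1)), seq_len(n)),
             arm = config$arm),
      covs |> mutate(sex = ifelse(.data$sex_male == 1, "male", "female"),
                     ecog = .data$ecog1) |>
        select("age", "sex", "ecog", "histology_adeno", "liver_met",
               "prior_lines_ge2", "prior_targeted"),
      tibble(
        pfs_time = pmin(pfs_latent, censor),
        pfs_event = as.integer(pfs_latent <= censor),
        os_time = pmin(os_latent, censor),
        os_event = as.integer(os_latent <= censor)
      )
    )
    if (any(!is.finite(out$os_time))) {
      abort_config("non-finite follow-up produced non-finite times; use finite `followup_months` with `cure_fraction > 0`")
    }
    out
  })
}

# numeric covariate matrix in the MAIC encoding
covariate_matrix <- function(records, covariates = subject_covariate_names()) {
  cols <- map(covariates, function(v) {
    switch(v,
      age = records$age,
      sex_male = as.numeric(records$sex == "male"),
      ecog1 = as.numeric(records$ecog == 1),
      {
        if (!v %in% names(records)) abort_validation(sprintf("unknown covariate '%s'", v))
        as.numeric(records[[v]])
      })
  })
  m <- do.call(cbind, cols)
  colnames(m) <- covariates
  if (anyNA(m)) abort_validation("matched covariates must be non-missing in every record")
  m
}

#' Summarize baseline characteristics of a cohort
#'
#' Means (age) and proportions (binary covariates) over non-missing values,
#' in the encoding the matching-adjusted indirect comparison consumes.
#'
#' @param records subject-level tibble from [generate_ipd()].
#' @param covariates covariate names to summarize.
#' @return a `trial_summary`: list with `n` and named numeric `covariate_means`.
#' @export
summarize_baseline <- function(records, covariates = subject_covariate_names()) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort_validation("`records` must be a non-empty data frame of subjects")
  }
  m <- covariate_matrix(records, covariates)
  structure(list(n = nrow(records), covariate_means = colMeans(m)),
            class = "trial_summary")
}

#' @export
#' @exportS3Method
print.trial_summary <- function(x, ...) {
  cat(sprintf("<trial_summary> n = %d\n", x$n))
  print(round(x$covariate_means, 4))
  invisible(x)
}

#' @export
#' @exportS3Method
tidy.trial_summary <- function(x, ...) {
  tibble(covariate = names(x$covariate_means),
         value = unname(x$covariate_means))
}

#' Simulate a published aggregate survival read-out
#'
#' Simulates a hidden comparator cohort, computes its Kaplan-Meier estimate,
#' and emits the digitized-curve representation a reader of a published figure
#' would have: survival read off at chosen times plus a numbers-at-risk table.
#' Used to exercise pseudo-IPD reconstruction against known ground truth.
#'
#' @param config a [cohort_config()] for the hidden cohort.
#' @param readoff_times times (months) at which survival is read off the curve.
#' @param risk_times times of the numbers-at-risk table (defaults to
#'   `readoff_times`).
#' @param endpoint `"os"` or `"pfs"`.
#' @param keep_cohort keep the hidden cohort as `attr(, "cohort")` (test mode).
#' @return a [digitized_km()] object.
#' @export
generate_aggregate_trial <- function(config, readoff_times,
                                     risk_times = NULL,
                                     endpoint = c("os", "pfs"),
                                     keep_cohort = FALSE) {
  endpoint <- arg_match(endpoint)
  cohort <- generate_ipd(config)
  time <- cohort[[paste0(endpoint, "_time")]]
  event <- cohort[[paste0(endpoint, "_event")]]
  if (any(readoff_times > max(time))) {
    abort_validation("`readoff_times` extend beyond the last follow-up time")
  }
  km <- km_estimate(cohort, endpoint = endpoint)
  surv <- survival_step_at(km, readoff_times)
  risk_times <- risk_times %||% readoff_times
  obs_time <- time
  n_risk <- vapply(risk_times, function(t) sum(obs_time >= t), numeric(1))
  dk <- digitized_km(
    curve = tibble(time = readoff_times, survival = surv),
    risk_table = tibble(time = risk_times, n_risk = n_risk),
    total_events = sum(event)
  )
  if (keep_cohort) attr(dk, "cohort") <- cohort
  dk
}

#' Write / read subject-level data as CSV
#'
#' @param records tibble from [generate_ipd()].
#' @param path file path.
#' @return `read_ipd_csv` returns the records tibble; `write_ipd_csv` returns
#'   `path` invisibly.
#' @export
write_ipd_csv <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_ipd_csv
#' @export
read_ipd_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
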