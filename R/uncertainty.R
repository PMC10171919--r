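# Uncertainty suite: one-way sensitivity analysis with +/-20% bounds, a
# probabilistic sensitivity analysis (beta for probabilities and utility
# weights, gamma for costs, multivariate normal on the unconstrained scale
# via the Cholesky factor of each survival fit's covariance), acceptability
# curves, and the published scenario set.

#' Parameter registry for sensitivity analyses
#'
#' Enumerates every economic parameter (all per-arm costs, adverse-event
#' incidences / management costs / disutilities, the two state utilities)
#' plus both discount rates. Bounds are +/-20% of the base value (utilities
#' capped at 1); PSA distributions are gamma for costs, beta for
#' probabilities and (dis)utility weights, and `fixed` for discount rates and
#' zero-valued parameters.
#'
#' @param inputs an `econ_inputs`.
#' @return tibble: `name`, `base`, `low`, `high`, `dist`.
#' @export
param_registry <- function(inputs) {
  rows <- list()
  add <- function(name, base, dist, cap1 = FALSE) {
    low <- 0.8 * base
    high <- 1.2 * base
    if (cap1) high <- min(high, 1)
    if (base == 0) dist <- "fixed"
    rows[[length(rows) + 1]] <<- tibble(name = name, base = base,
                                        low = low, high = high, dist = dist)
  }
  for (arm in names(inputs$costs)) {
    for (item in names(inputs$costs[[arm]])) {
      add(sprintf("cost_%s_%s", arm, item), inputs$costs[[arm]][[item]], "gamma")
    }
  }
  for (i in seq_len(nrow(inputs$ae))) {
    r <- inputs$ae[i, ]
    add(sprintf("ae_%s_%s_incidence", r$arm, r$name), r$incidence, "beta", cap1 = TRUE)
    add(sprintf("ae_%s_%s_cost", r$arm, r$name), r$mgmt_cost, "gamma")
    add(sprintf("ae_%s_%s_disutility", r$arm, r$name), r$disutility, "beta", cap1 = TRUE)
  }
  add("u_pfs", inputs$u_pfs, "beta", cap1 = TRUE)
  add("u_pd", inputs$u_pd, "beta", cap1 = TRUE)
  add("discount_cost", inputs$discount_cost, "fixed")
  add("discount_qaly", inputs$discount_qaly, "fixed")
  list_rbind(rows)
}

set_param <- function(inputs, name, value) {
  m <- regmatches(name, regexec("^cost_(serplulimab|regorafenib)_(.+)$", name))[[1]]
  if (length(m) == 3) {
    inputs$costs[[m[2]]][[m[3]]] <- value
    return(inputs)
  }
  m <- regmatches(name, regexec(
    "^ae_(serplulimab|regorafenib)_(.+)_(incidence|cost|disutility)$", name))[[1]]
  if (length(m) == 4) {
    col <- c(incidence = "incidence", cost = "mgmt_cost",
             disutility = "disutility")[[m[4]]]
    idx <- inputs$ae$arm == m[2] & inputs$ae$name == m[3]
    if (!any(idx)) abort_config(sprintf("unknown adverse event in '%s'", name))
    inputs$ae[[col]][idx] <- value
    return(inputs)
  }
  if (name %in% c("u_pfs", "u_pd", "discount_cost", "discount_qaly", "wtp")) {
    inputs[[name]] <- value
    return(inputs)
  }
  abort_config(sprintf("unknown parameter '%s'", name))
}

# recompute the ICER on a run's existing traces under modified economic inputs
rebuild_economics <- function(run, inputs) {
  compute_icer(arm_result(run$ser$trace, inputs, "serplulimab"),
               arm_result(run$reg$trace, inputs, "regorafenib"),
               wtp = inputs$wtp)
}

#' One-way sensitivity analysis (tornado)
#'
#' Recomputes the ICER at each parameter's low and high bound, holding all
#' others at base, on the run's fixed traces (economic parameters do not
#' alter state occupancy). Rows are sorted by the width of the ICER range;
#' bounds that make the incremental QALYs zero are flagged rather than
#' dropped.
#'
#' @param run a `cea_run`.
#' @param registry parameter rows from [param_registry()] (subsettable).
#' @return an `owsa_result` tibble: name, base/low/high parameter values,
#'   `icer_base`, `icer_low`, `icer_high`, `range`, `degenerate`.
#' @export
owsa <- function(run, registry = param_registry(run$inputs)) {
  base_ce <- rebuild_economics(run, run$inputs)
  eval_at <- function(name, value) {
    ce <- rebuild_economics(run, set_param(run$inputs, name, value))
    list(icer = ce$icer, dq0 = ce$delta_qaly == 0)
  }
  out <- pmap(registry[c("name", "base", "low", "high")], function(name, base, low, high) {
    lo <- eval_at(name, low)
    hi <- eval_at(name, high)
    tibble(name = name, base = base, low = low, high = high,
           icer_base = base_ce$icer, icer_low = lo$icer, icer_high = hi$icer,
           degenerate = lo$dq0 || hi$dq0)
  }) |> list_rbind()
  out$range <- abs(out$icer_high - out$icer_low)
  out <- arrange(out, desc(.data$range))
  structure(out, class = c("owsa_result", class(out)))
}

#' Plot a tornado diagram
#'
#' @param object an `owsa_result`.
#' @param top number of parameters shown (widest ICER ranges first).
#' @param ... unused.
#' @return a ggplot.
#' @export
#' @exportS3Method
autoplot.owsa_result <- function(object, top = 10, ...) {
  d <- head(as_tibble(object), top)
  d$name <- factor(d$name, levels = rev(d$name))
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low, xend = .data$icer_high,
                                       y = .data$name, yend = .data$name),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = d$icer_base[1], linetype = 2) +
    ggplot2::labs(x = "ICER ($/QALY)", y = NULL) +
    ggplot2::theme_minimal()
}

beta_hyper <- function(mean, sd) {
  v <- sd^2
  if (v >= mean * (1 - mean)) {
    abort_config(sprintf(
      "beta moment matching infeasible for mean %.4f: SD must be < %.4f",
      mean, sqrt(mean * (1 - mean))))
  }
  nu <- mean * (1 - mean) / v - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

draw_econ_params <- function(registry, n_draws) {
  draws <- matrix(rep(registry$base, each = n_draws), nrow = n_draws)
  colnames(draws) <- registry$name
  for (i in seq_len(nrow(registry))) {
    r <- registry[i, ]
    if (r$dist == "fixed" || r$base == 0) next
    sd <- 0.2 * r$base
    if (r$dist == "gamma") {
      shape <- (r$base / sd)^2
      draws[, i] <- stats::rgamma(n_draws, shape = shape, rate = shape / r$base)
    } else if (r$dist == "beta") {
      h <- beta_hyper(r$base, sd)
      draws[, i] <- stats::rbeta(n_draws, h[1], h[2])
    }
  }
  draws
}

# replace a fit's parameters with a drawn unconstrained vector
with_theta <- function(fit, theta) {
  if (inherits(fit, "cure_fit")) {
    fit$pi <- plogis(theta[1])
    fit$latent$params <- surv_from_unconstrained(fit$latent$family, theta[-1])
  } else {
    fit$params <- surv_from_unconstrained(fit$family, theta)
  }
  fit$theta <- theta
  fit
}

draw_surv_thetas <- function(fit, n_draws, block_name) {
  vc <- fit$vcov
  if (anyNA(vc)) {
    abort_config(sprintf("survival block '%s' has no valid covariance", block_name))
  }
  L <- tryCatch(chol(vc + diag(1e-12, nrow(vc))), error = function(e) {
    abort_config(sprintf("survival block '%s': vcov is not positive semidefinite",
                         block_name))
  })
  z <- matrix(rnorm(n_draws * length(fit$theta)), nrow = n_draws)
  sweep(z %*% L, 2, fit$theta, `+`)
}

#' Probabilistic sensitivity analysis
#'
#' Draws every registry parameter from its assigned distribution
#' (hyperparameters by moment matching: mean = base, SD = 20% of base) and
#' every survival-fit block jointly from a multivariate normal on the
#' unconstrained parameter scale using the Cholesky factor of the fit's
#' covariance. Each draw re-derives the floored curves, transition schedules,
#' traces and economics from the drawn survival parameters. Reproducible for
#' a fixed seed.
#'
#' @param run a `cea_run`.
#' @param n_draws number of Monte Carlo draws (1000 in the published
#'   analysis).
#' @param seed integer seed.
#' @param registry parameter registry (defaults to the full set).
#' @return a `psa_draws` tibble: per draw, cost and QALY per arm plus
#'   `delta_cost`, `delta_qaly`.
#' @export
psa <- function(run, n_draws = 1000, seed = 1,
                registry = param_registry(run$inputs)) {
  if (n_draws < 1) abort_config("`n_draws` must be positive")
  run_with_seed(seed, {
    econ <- draw_econ_params(registry, n_draws)
    blocks <- list(
      ser_pfs = run$fits$ser_pfs$best, ser_os = run$fits$ser_os$best,
      reg_pfs = run$fits$reg_pfs$best, reg_os = run$fits$reg_os$best
    )
    thetas <- imap(blocks, function(f, nm) draw_surv_thetas(f, n_draws, nm))

    one_draw <- function(i) {
      inputs_i <- run$inputs
      for (j in seq_len(nrow(registry))) {
        if (econ[i, j] != registry$base[j]) {
          inputs_i <- set_param(inputs_i, registry$name[j], econ[i, j])
        }
      }
      fits_i <- map2(blocks, thetas, function(f, th) with_theta(f, th[i, ]))
      ser <- extrapolate_arm(fits_i$ser_pfs, fits_i$ser_os, run$life_table, run$config)
      reg <- extrapolate_arm(fits_i$reg_pfs, fits_i$reg_os, run$life_table, run$config)
      rs <- arm_result(ser$trace, inputs_i, "serplulimab")
      rr <- arm_result(reg$trace, inputs_i, "regorafenib")
      tibble(draw = i, cost_ser = rs$cost, qaly_ser = rs$qaly,
             cost_reg = rr$cost, qaly_reg = rr$qaly,
             cure_fraction_ser = if (inherits(fits_i$ser_os, "cure_fit"))
               fits_i$ser_os$pi else NA_real_)
    }
    out <- map(seq_len(n_draws), one_draw) |> list_rbind()
    out$delta_cost <- out$cost_ser - out$cost_reg
    out$delta_qaly <- out$qaly_ser - out$qaly_reg
    structure(out, class = c("psa_draws", class(out)),
              seed = seed, n_draws = n_draws)
  })
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with positive
#' net monetary benefit `lambda * delta_QALY - delta_cost`.
#'
#' @param draws a [psa()] result.
#' @param lambda_grid willingness-to-pay grid ($/QALY).
#' @return a `ceac_curve` tibble: `lambda`, `prob_cost_effective`.
#' @export
ceac <- function(draws, lambda_grid = seq(0, 60000, by = 500)) {
  prob <- vapply(lambda_grid, function(l) {
    mean(l * draws$delta_qaly - draws$delta_cost > 0)
  }, numeric(1))
  structure(tibble(lambda = lambda_grid, prob_cost_effective = prob),
            class = c("ceac_curve", class(tibble())))
}

#' Plot an acceptability curve
#'
#' @param object a `ceac_curve`.
#' @param wtp threshold marked with a vertical line ($36,036 default).
#' @param ... unused.
#' @return a ggplot.
#' @export
#' @exportS3Method
autoplot.ceac_curve <- function(object, wtp = 36036, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$lambda, y = .data$prob_cost_effective)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = wtp, linetype = 2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay ($/QALY)",
                  y = "Probability cost-effective") +
    ggplot2::theme_minimal()
}

SCENARIO_IDS <- c("no_maic", "horizon_36m", "death_risk_4x",
                  "utilities_astrum", "utilities_correct")

#' Run one published scenario
#'
#' Scenario overrides: `no_maic` uses unit weights (direct comparison);
#' `horizon_36m` truncates both traces to 39 complete 28-day cycles;
#' `death_risk_4x` re-floors the curves at 4x general-population mortality;
#' `utilities_astrum` / `utilities_correct` swap the utility set on identical
#' traces (same costs and life-years as the base case by construction).
#'
#' @param id scenario identifier: `"no_maic"`, `"horizon_36m"`,
#'   `"death_risk_4x"`, `"utilities_astrum"` or `"utilities_correct"`.
#' @param base_run the base-case `cea_run` the scenario deviates from.
#' @return a `scenario_result`: list with `id`, `arm_results`, `ce`.
#' @export
run_scenario <- function(id, base_run) {
  if (!id %in% SCENARIO_IDS) {
    abort_config(sprintf("unknown scenario id '%s' (expected one of %s)",
                         id, paste(SCENARIO_IDS, collapse = ", ")))
  }
  config <- base_run$config
  inputs <- base_run$inputs
  life_table <- base_run$life_table

  result <- switch(id,
    no_maic = {
      cfg2 <- config
      cfg2$use_maic <- FALSE
      run2 <- run_pipeline(cfg2)
      list(arm_results = run2$arm_results, ce = run2$ce)
    },
    horizon_36m = {
      tr_ser <- run_cohort(base_run$ser$schedule, horizon = "fixed",
                           n_cycles = config$n_cycles_fixed)
      tr_reg <- run_cohort(base_run$reg$schedule, horizon = "fixed",
                           n_cycles = config$n_cycles_fixed)
      rs <- arm_result(tr_ser, inputs, "serplulimab")
      rr <- arm_result(tr_reg, inputs, "regorafenib")
      list(arm_results = bind_rows(rs, rr),
           ce = compute_icer(rs, rr, wtp = inputs$wtp))
    },
    death_risk_4x = {
      cfg2 <- config
      cfg2$k <- 4
      ser <- extrapolate_arm(base_run$fits$ser_pfs$best, base_run$fits$ser_os$best,
                             life_table, cfg2)
      reg <- extrapolate_arm(base_run$fits$reg_pfs$best, base_run$fits$reg_os$best,
                             life_table, cfg2)
      rs <- arm_result(ser$trace, inputs, "serplulimab")
      rr <- arm_result(reg$trace, inputs, "regorafenib")
      list(arm_results = bind_rows(rs, rr),
           ce = compute_icer(rs, rr, wtp = inputs$wtp))
    },
    utilities_astrum = ,
    utilities_correct = {
      set <- sub("^utilities_", "", id)
      inputs2 <- load_econ_inputs(
        dir = config$inputs_dir, utility_set = set,
        discount_cost = config$discount_cost, discount_qaly = config$discount_qaly,
        wtp = config$wtp)
      rs <- arm_result(base_run$ser$trace, inputs2, "serplulimab")
      rr <- arm_result(base_run$reg$trace, inputs2, "regorafenib")
      list(arm_results = bind_rows(rs, rr),
           ce = compute_icer(rs, rr, wtp = inputs2$wtp))
    }
  )
  structure(c(list(id = id), result), class = "scenario_result")
}

#' @export
#' @exportS3Method
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s\n", x$id))
  print(x$ce)
  invisible(x)
}

#' @export
#' @exportS3Method
glance.scenario_result <- function(x, ...) {
  bind_cols(tibble(scenario = x$id), glance(x$ce))
}
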