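# Maximum-likelihood fitting of the six standard parametric families and a
# mixture cure model to (optionally frequency-weighted) censored data.
# Optimisation runs on unconstrained scales (log for positive parameters,
# logit for the cure probability); the parameter covariance comes from the
# inverse observed information at the MLE, on the same unconstrained scale —
# which is exactly the scale on which probabilistic sensitivity analysis
# draws correlated parameter values.

resolve_fit_data <- function(records, endpoint, weights) {
  cols <- resolve_endpoint_columns(records, endpoint)
  if (is.null(weights) && ".maic_weight" %in% names(records)) {
    weights <- records$.maic_weight
  }
  if (is.null(weights)) weights <- rep(1, length(cols$time))
  if (any(weights < 0)) abort_validation("weights must be nonnegative")
  keep <- weights > 0
  list(time = cols$time[keep], event = cols$event[keep], w = weights[keep])
}

weighted_loglik <- function(family, params, time, event, w) {
  # extreme optimizer trial values can make the stats d* functions warn and
  # return NaN; those iterates are rejected through the -Inf guard below
  d <- suppressWarnings(dens_parametric(family, params, time))
  s <- suppressWarnings(surv_parametric(family, params, time))
  lf <- log(pmax(ifelse(is.finite(d), d, 0), 1e-300))
  ls <- log(pmax(ifelse(is.finite(s), s, 0), 1e-300))
  sum(w * ifelse(event == 1, lf, ls))
}

#' Fit a parametric survival distribution by maximum likelihood
#'
#' Maximizes the frequency-weighted censored-data log-likelihood
#' `sum w_i (delta_i log f(t_i) + (1 - delta_i) log S(t_i))` under the
#' package's fixed parameterizations (see [surv_parametric()]).
#'
#' @param records subject-level tibble (a `.maic_weight` column is honoured).
#' @param endpoint `"os"` or `"pfs"`.
#' @param family one of the six families in `SURV_FAMILIES`.
#' @param weights optional nonnegative frequency weights.
#' @return a `surv_fit`: family, natural `params`, unconstrained `theta`,
#'   `loglik`, `aic`, `bic`, `vcov` (unconstrained scale), `n_eff` (sum of
#'   weights, used in the BIC).
#' @export
fit_parametric <- function(records, endpoint = c("os", "pfs"),
                           family = SURV_FAMILIES, weights = NULL) {
  endpoint <- arg_match(endpoint)
  family <- arg_match(family)
  dat <- resolve_fit_data(records, endpoint, weights)
  if (sum(dat$w * dat$event) <= 0) abort_validation("need at least one event to fit")

  negll <- function(theta) {
    p <- surv_from_unconstrained(family, theta)
    -weighted_loglik(family, p, dat$time, dat$event, dat$w)
  }
  start <- surv_to_unconstrained(family, surv_start_values(family, dat$time, dat$event, dat$w))
  starts <- list(start, start + 0.5, start - 0.5)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, negll, method = "BFGS", control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) abort_validation(sprintf("fit of family '%s' failed from all starts", family))

  theta <- best$par
  H <- tryCatch(optimHess(theta, negll), error = function(e) NULL)
  vc <- safe_inverse(H, length(theta))
  params <- surv_from_unconstrained(family, theta)
  k <- length(theta)
  ll <- -best$value
  n_eff <- sum(dat$w)
  structure(list(
    family = family, params = params, theta = theta,
    loglik = ll, aic = 2 * k - 2 * ll, bic = k * log(n_eff) - 2 * ll,
    vcov = vc, n_eff = n_eff, n_params = k,
    endpoint = endpoint, converged = best$convergence == 0
  ), class = "surv_fit")
}

safe_inverse <- function(H, k) {
  vc <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  if (is.null(vc)) vc <- matrix(NA_real_, k, k)
  vc <- (vc + t(vc)) / 2
  vc
}

#' Fit a mixture cure survival model
#'
#' Mixture cure form `S(t) = pi + (1 - pi) S_u(t)` with an uncured latent
#' distribution from one of the six parametric families; the MLE is taken
#' over `(logit pi, latent parameters)` with a multi-start over
#' `pi in {0.1, ..., 0.7}`. Intended for curves with a long-term-survivor
#' plateau (immature OS of responders to immunotherapy); a warning is issued
#' when follow-up shows no censored tail beyond the last event, in which case
#' the plateau is weakly identified.
#'
#' @inheritParams fit_parametric
#' @param latent_family parametric family of the uncured component.
#' @return a `cure_fit`: `pi`, `latent` (family + natural params), `theta`
#'   (logit pi then unconstrained latent), `loglik`/`aic`/`bic`, `vcov` on the
#'   unconstrained scale, `boundary` flag when `pi` is pinned near 0 or 1.
#' @export
fit_mixture_cure <- function(records, endpoint = c("os", "pfs"),
                             latent_family = "lognormal", weights = NULL) {
  endpoint <- arg_match(endpoint)
  if (!latent_family %in% SURV_FAMILIES) {
    abort_config(sprintf("unknown latent family '%s'", latent_family))
  }
  dat <- resolve_fit_data(records, endpoint, weights)
  if (sum(dat$w * dat$event) <= 0) abort_validation("need at least one event to fit")
  last_event <- max(dat$time[dat$event == 1])
  if (max(dat$time) <= last_event) {
    warn("no censored follow-up beyond the last event; the cure plateau is weakly identified")
  }

  negll <- function(theta) {
    pi <- plogis(theta[1])
    p <- surv_from_unconstrained(latent_family, theta[-1])
    s <- pi + (1 - pi) * suppressWarnings(surv_parametric(latent_family, p, dat$time))
    f <- (1 - pi) * suppressWarnings(dens_parametric(latent_family, p, dat$time))
    f <- ifelse(is.finite(f), f, 0)
    -sum(dat$w * ifelse(dat$event == 1,
                        log(pmax(f, 1e-300)), log(pmax(s, 1e-300))))
  }
  latent_start <- surv_to_unconstrained(
    latent_family, surv_start_values(latent_family, dat$time, dat$event, dat$w))
  best <- NULL
  for (pi0 in seq(0.1, 0.7, by = 0.1)) {
    s0 <- c(qlogis(pi0), latent_start)
    fit <- tryCatch(
      optim(s0, negll, method = "BFGS", control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) abort_validation("mixture cure fit failed from all starts")

  theta <- best$par
  pi_hat <- plogis(theta[1])
  boundary <- pi_hat < 1e-3 || pi_hat > 1 - 1e-3
  if (boundary) warn(sprintf("cure fraction pinned at boundary (pi = %.4f)", pi_hat))
  H <- tryCatch(optimHess(theta, negll), error = function(e) NULL)
  vc <- safe_inverse(H, length(theta))
  k <- length(theta)
  ll <- -best$value
  n_eff <- sum(dat$w)
  structure(list(
    pi = pi_hat,
    latent = list(family = latent_family,
                  params = surv_from_unconstrained(latent_family, theta[-1])),
    theta = theta,
    loglik = ll, aic = 2 * k - 2 * ll, bic = k * log(n_eff) - 2 * ll,
    vcov = vc, n_eff = n_eff, n_params = k,
    endpoint = endpoint, boundary = boundary, converged = best$convergence == 0
  ), class = "cure_fit")
}

#' Evaluate survival / hazard of a fitted model
#'
#' Closed-form survival and hazard of a `surv_fit` or `cure_fit` at arbitrary
#' times; the hazard is `f(t) / S(t)` with the survival guarded away from 0.
#'
#' @param fit a `surv_fit` or `cure_fit`.
#' @param t nonnegative times (months).
#' @return numeric vector.
#' @export
survival_at <- function(fit, t) UseMethod("survival_at")

#' @export
#' @exportS3Method
survival_at.surv_fit <- function(fit, t) surv_parametric(fit$family, fit$params, t)

#' @export
#' @exportS3Method
survival_at.cure_fit <- function(fit, t) {
  fit$pi + (1 - fit$pi) * surv_parametric(fit$latent$family, fit$latent$params, t)
}

#' @rdname survival_at
#' @export
hazard_at <- function(fit, t) UseMethod("hazard_at")

#' @export
#' @exportS3Method
hazard_at.surv_fit <- function(fit, t) haz_parametric(fit$family, fit$params, t)

#' @export
#' @exportS3Method
hazard_at.cure_fit <- function(fit, t) {
  f <- (1 - fit$pi) * dens_parametric(fit$latent$family, fit$latent$params, t)
  f / pmax(survival_at(fit, t), 1e-300)
}

#' Rank candidate survival fits by information criteria
#'
#' Ranks by AIC (BIC reported alongside); ties within 0.01 AIC are broken in
#' favour of fewer parameters. The selection can be overridden by name — the
#' published analyses' practice of combining information criteria with visual
#' inspection — in which case the full ranking is still attached.
#'
#' @param fits named list of `surv_fit` / `cure_fit` objects.
#' @param override optional name in `fits` to force as the selection.
#' @return list with `best` (the chosen fit), `choice` (its name) and
#'   `ranking` (a tibble: name, k, loglik, aic, bic, rank).
#' @export
select_best <- function(fits, override = NULL) {
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- map_chr_fit(fits)
  }
  ranking <- imap(fits, function(f, nm) {
    tibble(name = nm, k = f$n_params, loglik = f$loglik, aic = f$aic, bic = f$bic)
  }) |> list_rbind()
  ord <- order(round(ranking$aic / 0.01) * 0.01, ranking$k)
  ranking <- ranking[ord, ]
  ranking$rank <- seq_len(nrow(ranking))
  choice <- if (!is.null(override)) {
    if (!override %in% names(fits)) {
      abort_config(sprintf("override '%s' is not among the candidate fits", override))
    }
    override
  } else ranking$name[1]
  list(best = fits[[choice]], choice = choice, ranking = as_tibble(ranking))
}

map_chr_fit <- function(fits) {
  vapply(fits, function(f) {
    if (inherits(f, "cure_fit")) paste0("cure_", f$latent$family) else f$family
  }, character(1))
}

#' @export
#' @exportS3Method
print.surv_fit <- function(x, ...) {
  cat(sprintf("<surv_fit> %s (%s), loglik = %.3f, AIC = %.3f\n",
              x$family, attr(x, "endpoint") %||% x$endpoint, x$loglik, x$aic))
  print(round(x$params, 5))
  invisible(x)
}

#' @export
#' @exportS3Method
print.cure_fit <- function(x, ...) {
  cat(sprintf("<cure_fit> pi = %.3f + %s latent, loglik = %.3f, AIC = %.3f\n",
              x$pi, x$latent$family, x$loglik, x$aic))
  print(round(x$latent$params, 5))
  invisible(x)
}

#' @export
#' @exportS3Method
tidy.surv_fit <- function(x, ...) {
  se <- sqrt(pmax(diag(x$vcov), 0))
  tibble(term = names(x$params), estimate = unname(x$params),
         theta = unname(x$theta), std_error_theta = se)
}

#' @export
#' @exportS3Method
tidy.cure_fit <- function(x, ...) {
  se <- sqrt(pmax(diag(x$vcov), 0))
  tibble(term = c("cure_fraction", names(x$latent$params)),
         estimate = c(x$pi, unname(x$latent$params)),
         theta = unname(x$theta), std_error_theta = se)
}

#' @export
#' @exportS3Method
glance.surv_fit <- function(x, ...) {
  tibble(family = x$family, k = x$n_params, loglik = x$loglik,
         aic = x$aic, bic = x$bic, n_eff = x$n_eff, converged = x$converged)
}

#' @export
#' @exportS3Method
glance.cure_fit <- function(x, ...) {
  tibble(family = paste0("cure_", x$latent$family), k = x$n_params,
         loglik = x$loglik, aic = x$aic, bic = x$bic, n_eff = x$n_eff,
         cure_fraction = x$pi, boundary = x$boundary, converged = x$converged)
}

#' Plot a fitted survival model against a Kaplan-Meier curve
#'
#' @param object a `surv_fit` or `cure_fit`.
#' @param km optional `km_fit` overlay.
#' @param horizon plotting horizon in months.
#' @param ... unused.
#' @return a ggplot.
#' @export
#' @exportS3Method
autoplot.surv_fit <- function(object, km = NULL, horizon = 60, ...) {
  plot_fit_curve(object, km, horizon)
}

#' @rdname autoplot.surv_fit
#' @export
#' @exportS3Method
autoplot.cure_fit <- function(object, km = NULL, horizon = 60, ...) {
  plot_fit_curve(object, km, horizon)
}

plot_fit_curve <- function(object, km, horizon) {
  grid <- tibble(time = seq(0, horizon, length.out = 301),
                 survival = survival_at(object, seq(0, horizon, length.out = 301)))
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability") +
    ggplot2::theme_minimal()
  if (!is.null(km)) {
    p <- p + ggplot2::geom_step(data = tidy(km), colour = "grey30")
  }
  p
}
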