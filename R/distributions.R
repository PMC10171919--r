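# Six standard parametric time-to-event families with fixed parameterizations:
#   exponential   rate lambda            S = exp(-lambda t)
#   weibull       shape kappa, scale s   S = exp(-(t/s)^kappa)
#   gamma         shape a, rate b        S = 1 - P(a, b t)   (regularized)
#   lognormal     meanlog mu, sdlog s    S = 1 - Phi((ln t - mu)/s)
#   loglogistic   scale alpha, shape b   S = 1 / (1 + (t/alpha)^b)
#   gompertz      rate lambda, shape g   h = lambda e^{g t}
# All positive parameters are optimised on the log scale; the Gompertz shape
# and the log-normal meanlog are unconstrained.

SURV_FAMILIES <- c("exponential", "gamma", "weibull", "lognormal",
                   "loglogistic", "gompertz")

surv_param_names <- function(family) {
  switch(family,
    exponential = "rate",
    weibull     = c("shape", "scale"),
    gamma       = c("shape", "rate"),
    lognormal   = c("meanlog", "sdlog"),
    loglogistic = c("scale", "shape"),
    gompertz    = c("rate", "shape"),
    abort_config(sprintf("unknown survival family '%s'", family))
  )
}

# which natural parameters live on the log scale during optimisation
surv_log_scale <- function(family) {
  switch(family,
    exponential = TRUE,
    weibull     = c(TRUE, TRUE),
    gamma       = c(TRUE, TRUE),
    lognormal   = c(FALSE, TRUE),
    loglogistic = c(TRUE, TRUE),
    gompertz    = c(TRUE, FALSE)
  )
}

surv_to_unconstrained <- function(family, params) {
  ifelse(surv_log_scale(family), log(params), params)
}

surv_from_unconstrained <- function(family, theta) {
  out <- ifelse(surv_log_scale(family), exp(theta), theta)
  setNames(out, surv_param_names(family))
}

#' Survival, density and hazard for the packaged parametric families
#'
#' Closed-form evaluation under the package's fixed parameterizations (see
#' the family table in the source for the exact forms).
#'
#' @param family one of `"exponential"`, `"gamma"`, `"weibull"`,
#'   `"lognormal"`, `"loglogistic"`, `"gompertz"`.
#' @param params numeric vector of natural parameters, in the order given by
#'   the family's parameter names (e.g. `c(shape, scale)` for Weibull).
#' @param t nonnegative times (months in this package's conventions).
#' @return numeric vector, same length as `t`.
#' @export
surv_parametric <- function(family, params, t) {
  p <- unname(params)
  switch(family,
    exponential = exp(-p[1] * t),
    weibull     = exp(-(t / p[2])^p[1]),
    gamma       = stats::pgamma(t, shape = p[1], rate = p[2], lower.tail = FALSE),
    lognormal   = ifelse(t <= 0, 1, stats::pnorm((log(pmax(t, 1e-300)) - p[1]) / p[2],
                                                 lower.tail = FALSE)),
    loglogistic = 1 / (1 + (t / p[1])^p[2]),
    gompertz    = {
      if (abs(p[2]) < 1e-12) exp(-p[1] * t)
      else exp(-(p[1] / p[2]) * (exp(p[2] * t) - 1))
    },
    abort_config(sprintf("unknown survival family '%s'", family))
  )
}

#' @rdname surv_parametric
#' @export
dens_parametric <- function(family, params, t) {
  p <- unname(params)
  switch(family,
    exponential = stats::dexp(t, rate = p[1]),
    weibull     = stats::dweibull(t, shape = p[1], scale = p[2]),
    gamma       = stats::dgamma(t, shape = p[1], rate = p[2]),
    lognormal   = stats::dlnorm(t, meanlog = p[1], sdlog = p[2]),
    loglogistic = {
      # log-scale evaluation avoids Inf/Inf overflow far in the tail
      lt <- log(pmax(t, 1e-300)) - log(p[1])
      out <- exp(log(p[2] / p[1]) + (p[2] - 1) * lt - 2 * log1p(exp(p[2] * lt)))
      big <- p[2] * lt > 700
      out[big] <- exp(log(p[2] / p[1]) + (-p[2] - 1) * lt[big])
      ifelse(t <= 0, if (p[2] > 1) 0 else if (p[2] == 1) p[2] / p[1] else Inf, out)
    },
    gompertz    = {
      if (abs(p[2]) < 1e-12) stats::dexp(t, rate = p[1])
      else exp(log(p[1]) + p[2] * t - (p[1] / p[2]) * expm1(p[2] * t))
    },
    abort_config(sprintf("unknown survival family '%s'", family))
  )
}

#' @rdname surv_parametric
#' @export
haz_parametric <- function(family, params, t) {
  s <- pmax(surv_parametric(family, params, t), 1e-300)
  dens_parametric(family, params, t) / s
}

# inverse-CDF random generation; Gompertz with negative shape has a defective
# distribution (plateau exp(rate/shape)) and returns Inf for the cured mass
rsurv_parametric <- function(n, family, params) {
  p <- unname(params)
  switch(family,
    exponential = stats::rexp(n, rate = p[1]),
    weibull     = stats::rweibull(n, shape = p[1], scale = p[2]),
    gamma       = stats::rgamma(n, shape = p[1], rate = p[2]),
    lognormal   = stats::rlnorm(n, meanlog = p[1], sdlog = p[2]),
    loglogistic = {
      u <- runif(n)
      p[1] * (u / (1 - u))^(1 / p[2])
    },
    gompertz    = {
      u <- runif(n)
      if (abs(p[2]) < 1e-12) return(-log(u) / p[1])
      arg <- 1 - (p[2] / p[1]) * log(u)
      ifelse(arg <= 0, Inf, log(arg) / p[2])
    },
    abort_config(sprintf("unknown survival family '%s'", family))
  )
}

# crude moment-based starting values on the natural scale
surv_start_values <- function(family, time, event, weights) {
  pos <- time > 0
  w <- weights[pos]
  t <- time[pos]
  mean_t <- weighted.mean(t, w)
  lt <- log(t)
  mu <- weighted.mean(lt, w)
  s2 <- weighted.mean((lt - mu)^2, w)
  rate0 <- sum(weights * event) / sum(weights * time)
  switch(family,
    exponential = c(rate = rate0),
    weibull     = c(shape = 1, scale = mean_t),
    gamma       = c(shape = 1, rate = rate0),
    lognormal   = c(meanlog = mu, sdlog = max(sqrt(s2), 0.2)),
    loglogistic = c(scale = exp(mu), shape = max(1 / max(sqrt(s2), 0.2), 0.5)),
    gompertz    = c(rate = rate0, shape = 0.01)
  )
}
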