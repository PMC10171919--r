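# Unanchored matching-adjusted indirect comparison. The intervention arm's
# individual patient data are reweighted so that weighted baseline moments
# equal the comparator trial's published moments. Weights take the
# entropy-balancing form w_i = exp(alpha' (x_i - x_target)); alpha solves the
# method-of-moments condition sum_i w_i (x_i - x_target) = 0, the gradient of
# the convex objective Q(alpha) = sum_i exp(alpha' (x_i - x_target)).

#' Fit matching-adjusted indirect comparison weights
#'
#' @param records intervention-arm subject-level tibble.
#' @param targets a `trial_summary` from [summarize_baseline()], or a named
#'   numeric vector of target means/proportions.
#' @param covariates covariates to match (must be present in `targets`).
#' @param tol convergence tolerance on the infinity norm of the gradient of
#'   the convex objective (per-subject scale).
#' @return a `maic_fit`: list with `alpha` (coefficients), `weights`
#'   (nonnegative, rescaled to sum to `n` — the frequency-weight convention),
#'   `ess` (effective sample size `(sum w)^2 / sum w^2`), `matched_covariates`,
#'   `achieved_means`, `target_means`.
#' @export
#' @examples
#' ipd <- generate_ipd(intervention_cohort_config(seed = 7, n = 100))
#' targets <- c(age = 57, sex_male = 0.6, ecog1 = 0.55)
#' fit <- fit_weights(ipd, targets, covariates = names(targets))
#' fit$ess
fit_weights <- function(records, targets,
                        covariates = NULL,
                        tol = 1e-8) {
  target_means <- if (inherits(targets, "trial_summary")) targets$covariate_means
                  else targets
  if (is.null(covariates)) covariates <- names(target_means)
  missing_t <- setdiff(covariates, names(target_means))
  if (length(missing_t) > 0) {
    abort_validation(sprintf("no target value for covariate(s): %s",
                             paste(missing_t, collapse = ", ")))
  }
  target_means <- target_means[covariates]
  X <- covariate_matrix(records, covariates)
  n <- nrow(X)

  # feasibility: each target must lie strictly inside the sample's support
  rng <- apply(X, 2, range)
  bad <- covariates[target_means <= rng[1, ] | target_means >= rng[2, ]]
  exact <- covariates[abs(target_means - colMeans(X)) < 1e-12 &
                        rng[1, ] == rng[2, ]]
  bad <- setdiff(bad, exact)  # degenerate column already equal to its target
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "target mean outside the convex hull of sample values for: %s",
      paste(bad, collapse = ", ")))
  }

  Z <- sweep(X, 2, target_means)
  keep <- apply(Z, 2, function(z) any(z != 0))
  qrz <- qr(Z[, keep, drop = FALSE])
  if (qrz$rank < sum(keep)) {
    dep <- colnames(Z[, keep, drop = FALSE])[-seq_len(qrz$rank)]
    dep2 <- setdiff(colnames(Z)[keep], colnames(Z[, keep, drop = FALSE])[qrz$pivot[seq_len(qrz$rank)]])
    abort_validation(sprintf("collinear matched covariates; dependent column(s): %s",
                             paste(if (length(dep2)) dep2 else dep, collapse = ", ")))
  }

  obj <- function(a) mean(exp(drop(Z[, keep, drop = FALSE] %*% a)))
  grad <- function(a) {
    w <- exp(drop(Z[, keep, drop = FALSE] %*% a))
    colMeans(Z[, keep, drop = FALSE] * w)
  }
  a0 <- rep(0, sum(keep))
  fit <- optim(a0, obj, grad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  # Newton polish to drive the moment conditions below tol
  a <- fit$par
  for (it in 1:50) {
    g <- grad(a)
    if (max(abs(g)) < tol) break
    w <- exp(drop(Z[, keep, drop = FALSE] %*% a))
    H <- crossprod(Z[, keep, drop = FALSE] * sqrt(w)) / n
    a <- a - solve(H + diag(1e-12, length(a)), g)
  }
  if (max(abs(grad(a))) > tol * 100) {
    abort_validation(paste0(
      "MAIC weight solver did not converge; a target is likely at or outside ",
      "the boundary of the sample support (gradient norm ",
      format(max(abs(grad(a))), digits = 3), ")"))
  }

  alpha <- setNames(rep(0, length(covariates)), covariates)
  alpha[keep] <- a
  w <- exp(drop(Z %*% alpha))
  w <- w * n / sum(w)
  achieved <- colSums(X * w) / sum(w)
  structure(list(
    alpha = alpha,
    weights = w,
    ess = sum(w)^2 / sum(w^2),
    n = n,
    matched_covariates = covariates,
    achieved_means = achieved,
    target_means = target_means
  ), class = "maic_fit")
}

#' Attach MAIC weights to a cohort
#'
#' Returns the records with a `.maic_weight` column; downstream
#' [km_estimate()] and the parametric/mixture-cure fitters pick the column up
#' automatically and treat it as frequency weights in risk sets and
#' likelihoods.
#'
#' @param records the cohort the weights were fitted on (same row order).
#' @param maic a `maic_fit`.
#' @return the weighted cohort tibble.
#' @export
apply_weights <- function(records, maic) {
  stopifnot(inherits(maic, "maic_fit"))
  if (nrow(records) != length(maic$weights)) {
    abort_validation("records and MAIC weights have different lengths")
  }
  mutate(as_tibble(records), .maic_weight = maic$weights)
}

#' @export
#' @exportS3Method
print.maic_fit <- function(x, ...) {
  cat(sprintf("<maic_fit> %d covariates matched, n = %d, ESS = %.1f\n",
              length(x$matched_covariates), x$n, x$ess))
  print(tidy(x), n = length(x$matched_covariates))
  invisible(x)
}

#' @export
#' @exportS3Method
tidy.maic_fit <- function(x, ...) {
  tibble(covariate = x$matched_covariates,
         alpha = unname(x$alpha),
         target = unname(x$target_means),
         achieved = unname(x$achieved_means))
}

#' @export
#' @exportS3Method
glance.maic_fit <- function(x, ...) {
  tibble(n = x$n, ess = x$ess,
         max_moment_error = max(abs(x$achieved_means - x$target_means)))
}

#' Plot MAIC weight distribution
#'
#' @param object a `maic_fit`.
#' @param ... unused.
#' @return a ggplot histogram of the rescaled weights.
#' @export
#' @exportS3Method
autoplot.maic_fit <- function(object, ...) {
  ggplot2::ggplot(tibble(weight = object$weights), ggplot2::aes(x = .data$weight)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::labs(x = "MAIC weight (rescaled to sum to n)", y = "Subjects",
                  subtitle = sprintf("ESS = %.1f of n = %d", object$ess, object$n)) +
    ggplot2::theme_minimal()
}
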