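# Pseudo individual-patient-data reconstruction from a digitized Kaplan-Meier
# curve plus its numbers-at-risk table (the Guyot algorithm). Within each
# risk-table interval the integer censoring count is adjusted iteratively so
# that the implied number at risk at the start of the next interval matches
# the published one, with per-point event counts recovered by inverting the
# product-limit ratios. Events are placed at the digitized step times; censor
# times are spread evenly inside their interval (events before censorings on
# ties, the standard KM convention).

#' Reconstruct pseudo individual patient data from a digitized KM curve
#'
#' @param dk a [digitized_km()] with curve coordinates and a risk table
#'   covering the curve span. When `total_events` is present in `dk`, the
#'   final-interval censoring count is adjusted towards the reported total as
#'   far as its censoring budget allows (exact matching is not always
#'   attainable, e.g. when no censoring precedes the last interval).
#' @return a tibble with columns `id`, `time`, `event` (one row per pseudo
#'   subject; covariates absent). Attributes: `diagnostics`, a per-point
#'   tibble of recovered event/censor counts.
#' @export
#' @examples
#' cfg <- comparator_cohort_config(seed = 42, n = 60)
#' dk <- generate_aggregate_trial(cfg, readoff_times = seq(0, 18, by = 1.5))
#' recon <- reconstruct_ipd(dk)
#' km_recon <- km_estimate(recon, endpoint = "os")
reconstruct_ipd <- function(dk) {
  stopifnot(inherits(dk, "digitized_km"))
  t_s <- dk$curve$time
  S <- dk$curve$survival
  rt <- dk$risk_table
  if (min(rt$time) > 0) {
    rt <- bind_rows(tibble(time = 0, n_risk = rt$n_risk[1]), rt)
  }
  rt <- filter(rt, .data$time <= max(t_s))
  t_risk <- rt$time
  n_risk <- rt$n_risk
  M <- length(t_risk)
  K <- length(t_s)

  lower <- upper <- integer(M)
  for (i in seq_len(M)) {
    lower[i] <- which(t_s >= t_risk[i])[1]
    hi <- if (i < M) t_risk[i + 1] else Inf
    upper[i] <- max(which(t_s < hi), lower[i] - 1L)
  }
  upper[M] <- K

  n_hat <- numeric(K + 1)
  d <- integer(K)
  cen <- integer(K)
  cen_times <- vector("list", K)
  km_hat <- numeric(K)
  n_censor_int <- integer(M)
  last_i <- integer(M)
  last_i[1] <- 1L

  # distribute `ncen` censor times evenly over (a, b] and bin them at the
  # curve points ks (censorings fall strictly inside the interval)
  distribute <- function(ncen, a, b, ks) {
    counts <- integer(length(ks))
    times <- vector("list", length(ks))
    if (ncen > 0 && b > a) {
      ct <- a + seq_len(ncen) * (b - a) / (ncen + 1)
      bins <- findInterval(ct, t_s[ks])
      bins[bins < 1] <- 1L
      for (j in seq_along(ks)) {
        times[[j]] <- ct[bins == j]
        counts[j] <- length(times[[j]])
      }
    }
    list(counts = counts, times = times)
  }

  # recover events/censors over one interval given its censor count;
  # returns state at the start of the next interval
  pass_interval <- function(i, ncen, commit = FALSE) {
    ks <- lower[i]:upper[i]
    if (upper[i] < lower[i]) {
      if (commit) n_hat[lower[i]] <<- n_risk[i]
      return(n_risk[i])
    }
    b_end <- if (i < M) t_s[min(lower[i + 1], K)] else t_s[K]
    dist <- distribute(ncen, t_s[lower[i]], b_end, ks)
    nh <- numeric(length(ks) + 1)
    dd <- integer(length(ks))
    kmh <- numeric(length(ks))
    nh[1] <- n_risk[i]
    last <- last_i[i]
    km_last <- if (last == 1) 1 else km_hat[last]
    for (j in seq_along(ks)) {
      k <- ks[j]
      if (k == 1) {
        dd[j] <- 0L
        kmh[j] <- 1
      } else {
        dd[j] <- if (nh[j] > 0 && km_last > 0) {
          as.integer(round(nh[j] * (1 - S[k] / km_last)))
        } else 0L
        dd[j] <- max(0L, min(dd[j], as.integer(floor(nh[j]))))
        kmh[j] <- if (nh[j] > 0) km_last * (1 - dd[j] / nh[j]) else km_last
      }
      nh[j + 1] <- nh[j] - dd[j] - dist$counts[j]
      if (dd[j] != 0) {
        last <- k
        km_last <- kmh[j]
      }
    }
    if (commit) {
      d[ks] <<- dd
      cen[ks] <<- dist$counts
      cen_times[ks] <<- dist$times
      km_hat[ks] <<- kmh
      n_hat[ks] <<- nh[seq_along(ks)]
      n_hat[upper[i] + 1] <<- nh[length(nh)]
      if (i < M) last_i[i + 1] <<- last
    }
    nh[length(nh)]
  }

  if (M > 1) {
    for (i in 1:(M - 1)) {
      s_lo <- S[lower[i]]
      ratio <- if (s_lo > 0) S[min(lower[i + 1], K)] / s_lo else 0
      ncen <- as.integer(round(n_risk[i] * ratio) - n_risk[i + 1])
      ncen <- max(0L, ncen)
      for (iter in 1:60) {
        nxt <- pass_interval(i, ncen)
        diff <- as.integer(round(nxt - n_risk[i + 1]))
        if (diff == 0 || (diff < 0 && ncen <= 0)) break
        ncen <- max(0L, ncen + diff)
      }
      n_censor_int[i] <- ncen
      pass_interval(i, ncen, commit = TRUE)
      if (n_hat[lower[i + 1]] < n_risk[i + 1]) n_risk[i + 1] <- n_hat[lower[i + 1]]
    }
  }

  # last interval: no published target; assume the average censoring rate of
  # earlier intervals, unless a total event count pins it down
  width_last <- t_s[K] - t_s[lower[M]]
  width_prev <- max(t_s[lower[M]] - t_s[1], 1e-12)
  ncen_last <- if (M > 1) {
    min(as.integer(round(sum(n_censor_int[1:(M - 1)]) * width_last / width_prev)),
        as.integer(n_risk[M]))
  } else 0L
  ncen_last <- max(0L, ncen_last)

  events_total_with <- function(ncen) {
    pass_interval(M, ncen, commit = TRUE)
    sum(d)
  }
  tot <- events_total_with(ncen_last)
  if (!is.null(dk$total_events)) {
    best <- list(ncen = ncen_last, err = abs(tot - dk$total_events))
    guard <- 0L
    while (tot != dk$total_events && guard < as.integer(n_risk[M]) + 2L) {
      step <- if (tot > dk$total_events) 1L else -1L
      ncen_last <- ncen_last + step
      if (ncen_last < 0L || ncen_last > n_risk[M]) break
      tot <- events_total_with(ncen_last)
      if (abs(tot - dk$total_events) < best$err) {
        best <- list(ncen = ncen_last, err = abs(tot - dk$total_events))
      }
      guard <- guard + 1L
    }
    if (tot != dk$total_events) events_total_with(best$ncen)
  }
  n_censor_int[M] <- ncen_last

  # assemble pseudo subjects; whoever is still at risk after the last curve
  # point is censored there
  times <- c(rep(t_s, d), unlist(cen_times), numeric(0))
  events <- c(rep(1L, sum(d)), rep(0L, length(unlist(cen_times))))
  leftover <- as.integer(round(n_hat[K + 1]))
  if (leftover > 0) {
    times <- c(times, rep(t_s[K], leftover))
    events <- c(events, rep(0L, leftover))
  }
  ord <- order(times, -events)  # events before censorings on ties
  out <- tibble(id = sprintf("R%04d", seq_along(times)),
                time = times[ord], event = events[ord])
  attr(out, "diagnostics") <- tibble(time = t_s, n_event = d, n_censor = cen,
                                     km_implied = km_hat)
  out
}
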