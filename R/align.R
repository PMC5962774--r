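#' Align spikes to events
#'
#' Collects, for each aligning event e, the relative times s - e of all
#' spikes s with s - e in the half-open window `[pre, post)`. A spike may
#' enter several trials when windows overlap. Events are trials: the raster
#' has one (possibly empty) trial per event.
#'
#' @param spikes A [spike_train()].
#' @param events An [event_train()]; must be nonempty.
#' @param window Length-2 numeric `c(pre, post)` with `pre <= 0 <= post`
#'   (seconds relative to the event).
#' @return An object of class `aligned_raster`: list with `trials` (list of
#'   numeric vectors of relative times), `window`, `n_trials`.
#' @export
align_spikes <- function(spikes, events, window = c(-0.5, 0.5)) {
  stopifnot(inherits(spikes, "spike_train"), inherits(events, "event_train"))
  if (length(events$times) == 0) stop("cannot align to an empty event train")
  if (length(window) != 2 || window[1] > 0 || window[2] < 0) {
    stop("window must be c(pre, post) with pre <= 0 <= post")
  }
  st <- spikes$times
  # half-open [pre, post): first spike >= e + pre .. last spike < e + post
  lo <- findInterval(events$times + window[1], st, left.open = TRUE) + 1L
  hi <- findInterval(events$times + window[2], st, left.open = TRUE)
  trials <- lapply(seq_along(events$times), function(i) {
    if (hi[i] < lo[i]) numeric(0) else st[lo[i]:hi[i]] - events$times[i]
  })
  structure(
    list(trials = trials, window = as.numeric(window),
         n_trials = length(trials)),
    class = "aligned_raster"
  )
}

#' @export
print.aligned_raster <- function(x, ...) {
  cat(sprintf("<aligned_raster> %d trials, window [%g, %g) s, %d spikes\n",
              x$n_trials, x$window[1], x$window[2],
              sum(lengths(x$trials))))
  invisible(x)
}

#' Peri-event time histogram
#'
#' Bins the pooled relative spike times of a raster into uniform half-open
#' bins `[left, right)` and normalizes counts to a trial-averaged rate in Hz:
#' `rate = counts / (n_trials * bin_width)`. If `bin_width` does not divide
#' the window length, the truncated final bin is dropped with a warning.
#'
#' @param raster An `aligned_raster` from [align_spikes()].
#' @param bin_width Bin width in seconds; must be positive and smaller than
#'   the window length.
#' @return An object of class `peth`: list with `bin_edges`, `counts`,
#'   `rate`, `n_trials`, `bin_width`.
#' @export
compute_peth <- function(raster, bin_width = 0.01) {
  stopifnot(inherits(raster, "aligned_raster"), bin_width > 0)
  win_len <- diff(raster$window)
  if (bin_width >= win_len) stop("bin_width must be smaller than the window")
  n_bins <- floor(win_len / bin_width + 1e-9)
  if (abs(n_bins * bin_width - win_len) > 1e-9 * max(1, win_len)) {
    warning("bin_width does not divide the window; dropping truncated final bin")
  }
  edges <- raster$window[1] + bin_width * (0:n_bins)
  rel <- unlist(raster$trials, use.names = FALSE)
  idx <- floor((rel - raster$window[1]) / bin_width) + 1
  idx <- idx[idx >= 1 & idx <= n_bins & rel < edges[n_bins + 1]]
  counts <- tabulate(idx, nbins = n_bins)
  structure(
    list(bin_edges = edges, counts = counts,
         rate = counts / (raster$n_trials * bin_width),
         n_trials = raster$n_trials, bin_width = bin_width),
    class = "peth"
  )
}

#' @export
print.peth <- function(x, ...) {
  cat(sprintf(
    "<peth> %d bins of %g s over [%g, %g) s, %d trials, peak rate %.2f Hz\n",
    length(x$counts), x$bin_width, x$bin_edges[1],
    x$bin_edges[length(x$bin_edges)], x$n_trials, max(x$rate)))
  invisible(x)
}

peth_bin_centers <- function(peth) {
  peth$bin_edges[-length(peth$bin_edges)] + peth$bin_width / 2
}

#' Fit a Gaussian bump to a PETH
#'
#' Least-squares fit of `r(t) = b + a * exp(-(t - mu)^2 / (2 sigma^2))` to
#' the per-bin rates at bin centers, via Levenberg-Marquardt with box bounds.
#' The initialization is deterministic: `b` at the median rate, `a` at
#' max - median, `mu` at the argmax bin center, `sigma` at twice the bin
#' width; `sigma` is constrained to (bin_width / 2, window length).
#' Non-convergence yields a flagged result (`converged = FALSE` with the
#' solver message), not an error.
#'
#' @param peth A `peth` from [compute_peth()] with at least 5 bins.
#' @return An object of class `gaussian_fit`: `baseline` (Hz), `amplitude`
#'   (Hz), `center` (s), `width` (s, the Gaussian sigma), `rss`, `converged`,
#'   `message`.
#' @export
fit_gaussian <- function(peth) {
  stopifnot(inherits(peth, "peth"))
  if (length(peth$counts) < 5) stop("need at least 5 bins to fit")
  t <- peth_bin_centers(peth)
  y <- peth$rate
  win_len <- diff(range(peth$bin_edges))
  start <- list(b = stats::median(y), a = max(y) - stats::median(y),
                mu = t[which.max(y)], sigma = 2 * peth$bin_width)
  lower <- c(b = -Inf, a = -Inf, mu = min(t), sigma = peth$bin_width / 2)
  upper <- c(b = Inf, a = Inf, mu = max(t), sigma = win_len)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b + a * exp(-(t - mu)^2 / (2 * sigma^2)),
      start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(
      list(baseline = start$b, amplitude = start$a, center = start$mu,
           width = start$sigma, rss = NA_real_, converged = FALSE,
           message = conditionMessage(fit)),
      class = "gaussian_fit"
    ))
  }
  cf <- stats::coef(fit)
  structure(
    list(baseline = unname(cf["b"]), amplitude = unname(cf["a"]),
         center = unname(cf["mu"]), width = unname(cf["sigma"]),
         rss = sum(stats::residuals(fit)^2), converged = TRUE,
         message = "converged"),
    class = "gaussian_fit"
  )
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf(
    "<gaussian_fit>%s b = %.3f Hz, a = %.3f Hz, mu = %.4f s, sigma = %.4f s, rss = %.3g\n",
    if (x$converged) "" else " [NOT CONVERGED]",
    x$baseline, x$amplitude, x$center, x$width, x$rss))
  invisible(x)
}

peak_rate_metric <- function(peth) max(peth$rate) - stats::median(peth$rate)

#' Degradation of event-locked metrics with event-timing noise
#'
#' For each timing-noise SD, runs fresh simulated sessions (one per seed),
#' aligns the spikes to the OBSERVED (noisy) events -- the train an
#' experimenter actually has -- and computes a response metric; reports mean
#' and SD across seeds. Metrics: `"peak_rate"` (peak PETH rate minus the
#' median baseline, the cross-correlation-peak analog), `"amplitude"` (fitted
#' Gaussian amplitude), `"peak_mi"` (maximum of the lagged mutual-information
#' function).
#'
#' @param config Base [simulation_config()]; its `event_jitter_sd` is
#'   overridden per sweep point and its `seed` offsets the per-run seeds.
#' @param noise_sds Numeric vector of timing-noise SDs (s).
#' @param n_seeds Number of independent sessions per noise level.
#' @param metric One of `"peak_rate"`, `"amplitude"`, `"peak_mi"`.
#' @param window,bin_width PETH window (s) and bin width (s).
#' @param mi_lags,mi_delta Lag grid (s) and time-bin width (s) for the
#'   `"peak_mi"` metric.
#' @return A data frame of class `degradation_curve` with columns
#'   `noise_sd`, `mean`, `sd`; attribute `metric` and per-run values in
#'   attribute `runs`.
#' @export
degradation_sweep <- function(config, noise_sds, n_seeds = 20,
                              metric = c("peak_rate", "amplitude", "peak_mi"),
                              window = c(-0.5, 0.5), bin_width = 0.01,
                              mi_lags = seq(-0.5, 0.5, by = 0.01),
                              mi_delta = 0.01) {
  metric <- match.arg(metric)
  stopifnot(n_seeds >= 1)
  runs <- matrix(NA_real_, nrow = n_seeds, ncol = length(noise_sds))
  for (j in seq_along(noise_sds)) {
    for (i in seq_len(n_seeds)) {
      cfg <- config
      cfg$event_jitter_sd <- noise_sds[j]
      cfg$seed <- config$seed + 1000L * (i - 1L) + j
      sim <- simulate_experiment(cfg)
      runs[i, j] <- switch(
        metric,
        peak_rate = peak_rate_metric(
          compute_peth(align_spikes(sim$spikes, sim$observed_events, window),
                       bin_width)),
        amplitude = fit_gaussian(
          compute_peth(align_spikes(sim$spikes, sim$observed_events, window),
                       bin_width))$amplitude,
        peak_mi = max(mi_lag_function(sim$observed_events, sim$spikes,
                                      delta = mi_delta, lags = mi_lags)$mi)
      )
    }
  }
  out <- data.frame(noise_sd = noise_sds,
                    mean = colMeans(runs),
                    sd = apply(runs, 2, stats::sd))
  attr(out, "metric") <- metric
  attr(out, "runs") <- runs
  class(out) <- c("degradation_curve", "data.frame")
  out
}
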