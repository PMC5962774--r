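#' Discretize a session into paired event/spike symbol sequences
#'
#' Cuts the time axis into half-open bins of width `delta`. `x[t]` is 1 iff
#' at least one event falls in bin t; `y[t]` is the spike count in bin t,
#' capped at `count_cap` (excess spikes lumped into the top category) to keep
#' the symbol alphabet small.
#'
#' @param session_duration Session length (s); must exceed `delta`.
#' @param events An [event_train()].
#' @param spikes A [spike_train()].
#' @param delta Bin width (s).
#' @param count_cap Maximum spike-count symbol (default 3).
#' @return A list of class `discretized_session`: `x` (0/1 integer), `y`
#'   (integer in 0..count_cap), `delta`, `n_bins`, `count_cap`; attribute
#'   `total_spikes` holds the pre-cap in-session spike count.
#' @export
discretize_session <- function(session_duration, events, spikes,
                               delta = 0.01, count_cap = 3L) {
  stopifnot(delta > 0, count_cap >= 1)
  if (delta >= session_duration) stop("delta must be smaller than the session")
  n_bins <- floor(session_duration / delta + 1e-9)
  bin_of <- function(times) {
    idx <- floor(times / delta) + 1
    idx[idx >= 1 & idx <= n_bins]
  }
  x <- integer(n_bins)
  x[unique(bin_of(events$times))] <- 1L
  ycounts <- tabulate(bin_of(spikes$times), nbins = n_bins)
  structure(
    list(x = x, y = pmin(ycounts, as.integer(count_cap)),
         delta = delta, n_bins = n_bins, count_cap = as.integer(count_cap)),
    class = "discretized_session",
    total_spikes = sum(ycounts)
  )
}

#' Plug-in mutual information between two symbol sequences
#'
#' Computes the plug-in estimate `sum p(x,y) log2[p(x,y) / (p(x) p(y))]` in
#' bits over the lag-shifted pairing `(x[t], y[t + lag_bins])`, trimming the
#' overhang. With `correction = "miller_madow"` the first-order bias term
#' `(Kx*Ky - Kx - Ky + 1) / (2 N ln 2)` (K = number of occupied categories)
#' is subtracted and the result floored at 0; the raw corrected value is
#' retained in the `"raw"` attribute.
#'
#' A constant (degenerate) sequence carries no information: the result is 0
#' with a warning.
#'
#' @param x,y Integer/numeric symbol sequences of equal length.
#' @param lag_bins Integer lag applied to `y` (positive: `y` later than `x`).
#' @param correction `"none"` or `"miller_madow"`.
#' @return Mutual information in bits (nonnegative after flooring), with the
#'   uncorrected/unfloored value in attribute `"raw"`.
#' @export
mutual_information <- function(x, y, lag_bins = 0L,
                               correction = c("none", "miller_madow")) {
  correction <- match.arg(correction)
  stopifnot(length(x) == length(y))
  n <- length(x)
  lag_bins <- as.integer(lag_bins)
  if (abs(lag_bins) >= n) stop("lag exceeds sequence length")
  if (lag_bins >= 0) {
    xs <- x[seq_len(n - lag_bins)]
    ys <- y[seq_len(n - lag_bins) + lag_bins]
  } else {
    xs <- x[seq_len(n + lag_bins) - lag_bins]
    ys <- y[seq_len(n + lag_bins)]
  }
  ux <- sort(unique(xs))
  uy <- sort(unique(ys))
  if (length(ux) < 2 || length(uy) < 2) {
    warning("degenerate (constant) sequence; MI is 0")
    return(structure(0, raw = 0))
  }
  joint <- joint_counts(xs, ys, ux, uy)
  mi <- plugin_mi_bits(joint)
  raw <- mi
  if (correction == "miller_madow") {
    kx <- sum(rowSums(joint) > 0)
    ky <- sum(colSums(joint) > 0)
    bias <- (kx * ky - kx - ky + 1) / (2 * sum(joint) * log(2))
    raw <- mi - bias
  }
  structure(max(raw, 0), raw = raw)
}

# joint contingency counts via a single tabulate pass (fast path for the
# lag sweep; equivalent to table(xs, ys))
joint_counts <- function(xs, ys, ux = sort(unique(xs)),
                         uy = sort(unique(ys))) {
  code <- (match(xs, ux) - 1L) * length(uy) + match(ys, uy)
  matrix(tabulate(code, nbins = length(ux) * length(uy)),
         nrow = length(ux), byrow = TRUE,
         dimnames = list(ux, uy))
}

# plug-in MI in bits from a joint contingency table
plugin_mi_bits <- function(joint) {
  n <- sum(joint)
  p <- joint / n
  px <- rowSums(p)
  py <- colSums(p)
  ind <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / ind[nz]))
}

#' Mutual information as a function of lag
#'
#' Evaluates [mutual_information()] between the binned event indicator and
#' the binned spike counts at each requested lag. With the convention used
#' here a positive lag pairs events with LATER spike bins, so an evoked
#' response at latency L peaks near `lag = L`.
#'
#' @param events An [event_train()].
#' @param spikes A [spike_train()].
#' @param delta Bin width (s).
#' @param lags Numeric vector of lags (s); rounded to whole bins. Must lie
#'   within +/- half the session.
#' @param correction Passed to [mutual_information()].
#' @param count_cap Passed to [discretize_session()].
#' @param session_duration Session length (s); defaults to the trains'
#'   recorded duration, else the last timestamp.
#' @return A data frame of class `mi_function` with columns `lag`, `mi`;
#'   attributes `delta`, `correction`, `n_bins`.
#' @export
mi_lag_function <- function(events, spikes, delta = 0.01,
                            lags = seq(-0.5, 0.5, by = 0.01),
                            correction = c("none", "miller_madow"),
                            count_cap = 3L, session_duration = NULL) {
  correction <- match.arg(correction)
  if (is.null(session_duration)) {
    session_duration <- if (!is.na(events$session_duration)) {
      events$session_duration
    } else {
      max(events$times, spikes$times)
    }
  }
  if (any(abs(lags) > session_duration / 2)) {
    stop("lags must lie within +/- half the session duration")
  }
  disc <- discretize_session(session_duration, events, spikes, delta,
                             count_cap)
  mi <- vapply(lags, function(l) {
    as.numeric(suppressWarnings(
      mutual_information(disc$x, disc$y, lag_bins = round(l / delta),
                         correction = correction)))
  }, numeric(1))
  out <- data.frame(lag = lags, mi = mi)
  attr(out, "delta") <- delta
  attr(out, "correction") <- correction
  attr(out, "n_bins") <- disc$n_bins
  class(out) <- c("mi_function", "data.frame")
  out
}

#' Shuffle null distribution for lagged mutual information
#'
#' Recomputes the MI at one lag after circularly shifting the spike train by
#' independent uniform random offsets. Circular shifting (rather than
#' permutation) preserves the inter-spike-interval structure of the train
#' while destroying its relation to the events, which makes the null share
#' the plug-in estimator's bias.
#'
#' @param events An [event_train()].
#' @param spikes A [spike_train()].
#' @param delta Bin width (s).
#' @param lag Lag (s) at which to evaluate.
#' @param n_shuffles Number of null draws, `>= 1`.
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @param correction,count_cap,session_duration As in [mi_lag_function()].
#' @return Numeric vector of `n_shuffles` null MI values (bits).
#' @export
shuffle_null <- function(events, spikes, delta = 0.01, lag = 0,
                         n_shuffles = 100, seed = NULL,
                         correction = c("none", "miller_madow"),
                         count_cap = 3L, session_duration = NULL) {
  correction <- match.arg(correction)
  stopifnot(n_shuffles >= 1)
  maybe_set_seed(seed)
  if (is.null(session_duration)) {
    session_duration <- if (!is.na(events$session_duration)) {
      events$session_duration
    } else {
      max(events$times, spikes$times)
    }
  }
  offsets <- stats::runif(n_shuffles, 0, session_duration)
  vapply(offsets, function(off) {
    shifted <- sort((spikes$times + off) %% session_duration)
    sh <- spike_train(shifted, session_duration = session_duration)
    disc <- discretize_session(session_duration, events, sh, delta, count_cap)
    as.numeric(suppressWarnings(
      mutual_information(disc$x, disc$y, lag_bins = round(lag / delta),
                         correction = correction)))
  }, numeric(1))
}
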