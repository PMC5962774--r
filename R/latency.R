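#' Pair command timestamps with actuation timestamps
#'
#' Greedy earliest-match: each command is matched to the earliest not yet
#' consumed actuation in `[command, command + max_lag)`; commands and
#' actuations left over on either side are reported as unmatched. When
#' consecutive commands are separated by more than `max_lag` (the intended
#' regime: one actuation per trial) the greedy match coincides with the
#' optimal assignment.
#'
#' @param commands Sorted numeric vector of command times (s).
#' @param actuations Sorted numeric vector of actuation times (s).
#' @param max_lag Maximum admissible delay (s), default 0.1.
#' @param channel Channel label carried through to the summary.
#' @return An object of class `delay_records`: data frame with columns
#'   `command_time`, `actuation_time`, `delay` (s); attributes
#'   `unmatched_commands` and `unmatched_actuations` (numeric vectors) and
#'   `channel`.
#' @export
pair_events <- function(commands, actuations, max_lag = 0.1,
                        channel = "default") {
  stopifnot(max_lag > 0)
  commands <- as.numeric(commands)
  actuations <- as.numeric(actuations)
  if (is.unsorted(commands) || is.unsorted(actuations)) {
    stop("commands and actuations must be sorted")
  }
  n_c <- length(commands)
  n_a <- length(actuations)
  match_of <- rep.int(NA_integer_, n_c)
  used <- logical(n_a)
  j <- 1L
  for (i in seq_len(n_c)) {
    # advance past actuations before this command or already consumed
    while (j <= n_a && (used[j] || actuations[j] < commands[i])) {
      j <- j + 1L
    }
    if (j <= n_a && actuations[j] < commands[i] + max_lag) {
      match_of[i] <- j
      used[j] <- TRUE
    }
  }
  hit <- !is.na(match_of)
  out <- data.frame(command_time = commands[hit],
                    actuation_time = actuations[match_of[hit]],
                    delay = actuations[match_of[hit]] - commands[hit])
  attr(out, "unmatched_commands") <- commands[!hit]
  attr(out, "unmatched_actuations") <- actuations[!used]
  attr(out, "channel") <- channel
  class(out) <- c("delay_records", "data.frame")
  out
}

#' Summarize a set of command-to-actuation delays
#'
#' Sample mean, unbiased (n - 1) SD, extremes and order-statistic percentiles
#' (1, 5, 50, 95, 99; linear interpolation) of the matched delays, plus the
#' unmatched counts. Percentile estimates from fewer than 20 pairs are
#' reported with a warning.
#'
#' @param records A `delay_records` from [pair_events()], or a bare numeric
#'   vector of delays (s).
#' @return An object of class `delay_summary`: list with `n`, `mean`, `sd`,
#'   `min`, `max`, `percentiles` (named numeric), `n_unmatched_commands`,
#'   `n_unmatched_actuations`, `channel`; all times in seconds.
#' @export
summarize_delays <- function(records) {
  if (inherits(records, "delay_records")) {
    delays <- records$delay
    n_uc <- length(attr(records, "unmatched_commands"))
    n_ua <- length(attr(records, "unmatched_actuations"))
    channel <- attr(records, "channel")
  } else {
    delays <- as.numeric(records)
    n_uc <- 0L
    n_ua <- 0L
    channel <- "default"
  }
  if (length(delays) == 0) stop("no matched delay records to summarize")
  if (length(delays) < 20) {
    warning("percentiles from fewer than 20 pairs are unreliable")
  }
  probs <- c(0.01, 0.05, 0.5, 0.95, 0.99)
  structure(
    list(n = length(delays), mean = mean(delays),
         sd = if (length(delays) > 1) stats::sd(delays) else 0,
         min = min(delays), max = max(delays),
         percentiles = stats::quantile(delays, probs, names = TRUE, type = 7),
         n_unmatched_commands = n_uc, n_unmatched_actuations = n_ua,
         channel = channel),
    class = "delay_summary"
  )
}

#' @export
print.delay_summary <- function(x, ...) {
  cat(sprintf(
    "<delay_summary '%s'> n = %d, mean = %.4f ms, SD = %.4f ms, range [%.4f, %.4f] ms\n",
    x$channel, x$n, x$mean * 1000, x$sd * 1000, x$min * 1000, x$max * 1000))
  if (x$n_unmatched_commands + x$n_unmatched_actuations > 0) {
    cat(sprintf("  unmatched: %d commands, %d actuations\n",
                x$n_unmatched_commands, x$n_unmatched_actuations))
  }
  invisible(x)
}

#' Compensate event times for a measured mean delivery latency
#'
#' Shifts each command timestamp forward by the measured mean delay, giving
#' the estimated actuation (delivery) times. The trial-to-trial jitter (the
#' delay SD) cannot be removed post hoc; it is attached as the
#' `"residual_jitter_sd"` attribute so downstream analyses can account for
#' the irreducible timing noise.
#'
#' @param event_times Numeric vector of command timestamps (s).
#' @param summary A `delay_summary` from [summarize_delays()].
#' @return Corrected times (s) with attribute `"residual_jitter_sd"`.
#' @export
compensate <- function(event_times, summary) {
  stopifnot(inherits(summary, "delay_summary"))
  structure(as.numeric(event_times) + summary$mean,
            residual_jitter_sd = summary$sd)
}

#' Simulate actuation times from commands plus random delays
#'
#' Fixture generator for the latency pipeline: each actuation is its command
#' time plus an independent random delay. `"normal"` draws are truncated at
#' zero (a delay cannot be negative) by resampling; `"shifted_gamma"` draws
#' `shift + Gamma(k, theta)` with k and theta matched to the requested mean
#' and SD (after removing the shift), for skewed valve-like delays.
#'
#' @param commands Sorted numeric vector of command times (s).
#' @param mean Mean delay (s), `> 0`.
#' @param sd Delay SD (s), `>= 0`.
#' @param distribution `"normal"` (zero-truncated) or `"shifted_gamma"`.
#' @param shift Fixed minimum delay (s) for the shifted-gamma model.
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return Sorted numeric vector of actuation times (s).
#' @export
simulate_delays <- function(commands, mean, sd,
                            distribution = c("normal", "shifted_gamma"),
                            shift = 0, seed = NULL) {
  distribution <- match.arg(distribution)
  stopifnot(mean > 0, sd >= 0)
  maybe_set_seed(seed)
  n <- length(commands)
  if (n == 0) return(numeric(0))
  delays <- if (sd == 0) {
    rep.int(mean, n)
  } else if (distribution == "normal") {
    d <- stats::rnorm(n, mean, sd)
    while (any(d <= 0)) {
      d[d <= 0] <- stats::rnorm(sum(d <= 0), mean, sd)
    }
    d
  } else {
    m <- mean - shift
    if (m <= 0) stop("shift must be below the mean delay")
    shape <- (m / sd)^2
    shift + stats::rgamma(n, shape = shape, scale = sd^2 / m)
  }
  sort(as.numeric(commands) + delays)
}
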