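#' Pure-tone specification
#'
#' A sine wave of a characteristic frequency with a unitless amplitude scale
#' in (0, 1], a duration and a sample rate. Amplitude 1 is full scale of the
#' playback chain.
#'
#' @param frequency Tone frequency (Hz); must be below Nyquist
#'   (`sample_rate / 2`).
#' @param amplitude Waveform scale in (0, 1].
#' @param duration Duration (s).
#' @param sample_rate Sample rate (Hz), default 44100.
#' @return An object of class `tone_spec`.
#' @export
tone_spec <- function(frequency, amplitude = 0.1, duration = 1,
                      sample_rate = 44100) {
  stopifnot(frequency > 0, duration > 0, sample_rate > 0)
  if (amplitude <= 0 || amplitude > 1) stop("amplitude must be in (0, 1]")
  if (frequency >= sample_rate / 2) {
    stop("frequency must be below the Nyquist frequency ", sample_rate / 2,
         " Hz")
  }
  structure(
    list(frequency = frequency, amplitude = amplitude, duration = duration,
         sample_rate = sample_rate),
    class = "tone_spec"
  )
}

new_waveform <- function(samples, sample_rate, clipped = FALSE) {
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate),
            class = "waveform", clipped = clipped)
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples at %g Hz (%.3f s), peak |amp| %.4f\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, max(abs(x$samples), 0)))
  invisible(x)
}

#' Generate a pure tone
#'
#' `samples[i] = A * sin(2 pi f i / sample_rate)` for `i = 0 .. N-1`,
#' `N = round(duration * sample_rate)`.
#'
#' @param spec A [tone_spec()].
#' @return A `waveform` (list of `samples`, `sample_rate`).
#' @export
generate_tone <- function(spec) {
  stopifnot(inherits(spec, "tone_spec"))
  n <- round(spec$duration * spec$sample_rate)
  i <- seq_len(n) - 1
  new_waveform(spec$amplitude * sin(2 * pi * spec$frequency * i / spec$sample_rate),
               spec$sample_rate)
}

#' Generate scaled Gaussian white noise
#'
#' i.i.d. standard normal samples scaled by `amplitude`: the digital
#' equivalent of `randn(1, duration * sample_rate) * A`. Note the samples are
#' not clipped to [-1, 1]; a Gaussian process exceeds any fixed scale with
#' positive probability, which matters only on export (see [write_wav()]).
#'
#' @param duration Duration (s), default 6.
#' @param amplitude Scale factor A, default 0.2.
#' @param sample_rate Sample rate (Hz), default 44100.
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return A `waveform`.
#' @export
generate_white_noise <- function(duration = 6, amplitude = 0.2,
                                 sample_rate = 44100, seed = NULL) {
  stopifnot(duration > 0, amplitude > 0, sample_rate > 0)
  maybe_set_seed(seed)
  n <- round(duration * sample_rate)
  new_waveform(stats::rnorm(n) * amplitude, sample_rate)
}

#' Single-step SPL amplitude update
#'
#' The closed-loop calibration rule: given a tone played at amplitude `A`
#' measured at `L` dB SPL, the amplitude expected to produce the target
#' `L0` dB SPL is `A0 = A * 10^((L0 - L) / 20)`. For a chain whose level is
#' linear in 20 log10(A) this is exact in one step. Results above full scale
#' are clipped to 1 and flagged via the `"clipped"` attribute.
#'
#' @param amplitude Current amplitude A, `> 0`.
#' @param level Measured level L (dB SPL).
#' @param target_level Target level L0 (dB SPL).
#' @return Updated amplitude A0 in (0, 1], attribute `"clipped"`.
#' @export
amplitude_update <- function(amplitude, level, target_level) {
  stopifnot(all(amplitude > 0))
  a0 <- amplitude * 10^((target_level - level) / 20)
  clipped <- a0 > 1
  a0[clipped] <- 1
  structure(a0, clipped = clipped)
}

#' Synthetic transducer backend
#'
#' Stands in for the physical speaker + microphone + spectrum-analyzer chain:
#' a played tone of amplitude A at frequency f is measured at
#' `L = 20 log10(A) + G(f) + offset (+ noise)` dB SPL. The default offset of
#' 94 dB maps full scale (A = 1) to 94 dB SPL, mirroring the 94 dB = 1 Pa
#' convention of microphone calibrators. Deterministic when `noise_sd = 0`.
#'
#' @param gain Frequency response G(f) in dB: a function of frequency, or a
#'   single number for a flat response (default 0).
#' @param noise_sd Measurement noise SD (dB), default 0.
#' @param offset Level (dB SPL) produced at amplitude 1 with G = 0.
#' @param label Backend identity string recorded in calibration tables.
#' @return An object of class `spl_backend`.
#' @export
synthetic_transducer <- function(gain = 0, noise_sd = 0, offset = 94,
                                 label = "synthetic") {
  gain_fun <- if (is.function(gain)) gain else function(f) rep(gain, length(f))
  stopifnot(noise_sd >= 0)
  structure(
    list(gain = gain_fun, noise_sd = noise_sd, offset = offset,
         label = label),
    class = "spl_backend"
  )
}

#' Measure the SPL of a tone through a backend
#'
#' @param backend An `spl_backend`.
#' @param frequency Tone frequency (Hz).
#' @param amplitude Tone amplitude in (0, 1].
#' @return Measured level in dB SPL.
#' @export
measure_spl <- function(backend, frequency, amplitude) {
  UseMethod("measure_spl")
}

#' @export
measure_spl.spl_backend <- function(backend, frequency, amplitude) {
  stopifnot(all(amplitude > 0))
  level <- 20 * log10(amplitude) + backend$gain(frequency) + backend$offset
  if (backend$noise_sd > 0) {
    level <- level + stats::rnorm(length(level), 0, backend$noise_sd)
  }
  level
}

#' Closed-loop per-frequency SPL calibration
#'
#' For each frequency: play at the current amplitude (via the backend),
#' measure L, apply the [amplitude_update()] rule, and repeat until
#' `|L - L0| <= tolerance` or `max_iter` is reached. With
#' `single_step = TRUE` exactly one update is applied and then verified by a
#' final measurement -- sufficient for a linear chain. Frequencies that do
#' not converge are flagged in the table rather than raising an error.
#'
#' @param backend An `spl_backend`.
#' @param freqs Frequencies to calibrate (Hz); default 1-21 kHz at 1 kHz
#'   steps.
#' @param target_level Target L0 (dB SPL), default 60.
#' @param tolerance Convergence tolerance (dB), default 0.5.
#' @param max_iter Maximum number of measure/update cycles.
#' @param start_amplitude Initial amplitude for every frequency.
#' @param single_step Apply the update once and verify, instead of iterating.
#' @param seed Optional seed for backends with measurement noise.
#' @return A data frame of class `calibration_table` with columns
#'   `frequency`, `amplitude` (A0), `level` (achieved dB SPL), `residual`
#'   (level - target), `iterations`, `converged`, `clipped`; attributes
#'   `target_level`, `backend`, `created`.
#' @export
calibrate_frequencies <- function(backend,
                                  freqs = seq(1000, 21000, by = 1000),
                                  target_level = 60, tolerance = 0.5,
                                  max_iter = 10, start_amplitude = 0.1,
                                  single_step = FALSE, seed = NULL) {
  stopifnot(length(freqs) >= 1, tolerance > 0, max_iter >= 1)
  maybe_set_seed(seed)
  rows <- lapply(freqs, function(f) {
    a <- start_amplitude
    level <- measure_spl(backend, f, a)
    iterations <- 0L
    clipped <- FALSE
    if (single_step) {
      a_new <- amplitude_update(a, level, target_level)
      clipped <- attr(a_new, "clipped")
      a <- as.numeric(a_new)
      level <- measure_spl(backend, f, a)
      iterations <- 1L
    } else {
      while (abs(level - target_level) > tolerance && iterations < max_iter) {
        a_new <- amplitude_update(a, level, target_level)
        clipped <- clipped || attr(a_new, "clipped")
        a <- as.numeric(a_new)
        level <- measure_spl(backend, f, a)
        iterations <- iterations + 1L
      }
    }
    data.frame(frequency = f, amplitude = a, level = level,
               residual = level - target_level, iterations = iterations,
               converged = abs(level - target_level) <= tolerance,
               clipped = clipped)
  })
  out <- do.call(rbind, rows)
  attr(out, "target_level") <- target_level
  attr(out, "backend") <- backend$label
  attr(out, "created") <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  class(out) <- c("calibration_table", "data.frame")
  out
}

#' Calibrated white-noise amplitude from anchor frequencies
#'
#' Measures the backend at each anchor frequency with the pre-assigned
#' starting amplitude, applies the single-step [amplitude_update()] rule per
#' anchor, and returns the arithmetic mean of the per-anchor amplitudes A0 --
#' an amplitude average, not a dB average (these differ for nonflat chains).
#'
#' @param backend An `spl_backend`.
#' @param target_level Target L0 (dB SPL).
#' @param anchor_freqs Anchor frequencies (Hz); default 1, 2, 5, 10, 20 kHz.
#' @param start_amplitude Pre-assigned white-noise amplitude, default 0.2.
#' @param seed Optional seed for noisy backends.
#' @return White-noise amplitude (scalar); per-anchor A0 values in attribute
#'   `"anchors"`.
#' @export
calibrate_white_noise <- function(backend, target_level = 60,
                                  anchor_freqs = c(1, 2, 5, 10, 20) * 1000,
                                  start_amplitude = 0.2, seed = NULL) {
  stopifnot(length(anchor_freqs) >= 1)
  maybe_set_seed(seed)
  a0 <- vapply(anchor_freqs, function(f) {
    level <- measure_spl(backend, f, start_amplitude)
    upd <- amplitude_update(start_amplitude, level, target_level)
    if (attr(upd, "clipped")) {
      stop("anchor at ", f, " Hz requires amplitude above full scale")
    }
    as.numeric(upd)
  }, numeric(1))
  if (any(!is.finite(a0)) || any(a0 <= 0)) {
    stop("white-noise calibration failed at an anchor frequency")
  }
  structure(mean(a0), anchors = stats::setNames(a0, anchor_freqs))
}

# amplitude for an arbitrary target level from a table entry:
# A* = A0 * 10^((L* - L0) / 20)
table_amplitude <- function(table, frequency, level) {
  l0 <- attr(table, "target_level")
  fr <- table$frequency
  if (frequency < min(fr) || frequency > max(fr)) {
    stop("frequency ", frequency, " Hz outside the calibrated range [",
         min(fr), ", ", max(fr), "] Hz")
  }
  hit <- which(abs(fr - frequency) < 1e-6)
  interpolated <- length(hit) == 0
  a0 <- if (interpolated) {
    # uncalibrated frequency: log-frequency linear interpolation of A0
    stats::approx(log(fr), table$amplitude, xout = log(frequency))$y
  } else {
    table$amplitude[hit[1]]
  }
  astar <- a0 * 10^((level - l0) / 20)
  if (astar > 1) {
    stop("requested level ", level, " dB SPL at ", frequency,
         " Hz is undeliverable (amplitude ", signif(astar, 4), " > 1)")
  }
  structure(astar, interpolated = interpolated)
}

#' Synthesize an equalized tone or tone mixture from a calibration table
#'
#' Per-component amplitudes for an arbitrary target level L* are scaled from
#' the table entries as `A* = A0 * 10^((L* - L0) / 20)`; frequencies between
#' table entries use log-frequency linear interpolation of A0 (flagged in the
#' `"interpolated"` attribute). Mixture components are synthesized
#' independently and summed (additive synthesis; no loudness summation).
#'
#' @param table A `calibration_table`.
#' @param frequency Frequency (Hz), or vector of frequencies for a mixture.
#' @param level Target level L* (dB SPL) applied to each component.
#' @param duration Duration (s).
#' @param sample_rate Sample rate (Hz).
#' @return A `waveform`; attributes `amplitudes` (per component) and
#'   `interpolated` (logical per component).
#' @export
synthesize_calibrated <- function(table, frequency, level, duration = 1,
                                  sample_rate = 44100) {
  stopifnot(inherits(table, "calibration_table"), length(frequency) >= 1)
  amps <- lapply(frequency, table_amplitude, table = table, level = level)
  n <- round(duration * sample_rate)
  i <- seq_len(n) - 1
  samples <- numeric(n)
  for (k in seq_along(frequency)) {
    samples <- samples +
      as.numeric(amps[[k]]) * sin(2 * pi * frequency[k] * i / sample_rate)
  }
  out <- new_waveform(samples, sample_rate)
  attr(out, "amplitudes") <- vapply(amps, as.numeric, numeric(1))
  attr(out, "interpolated") <- vapply(amps, attr, logical(1), "interpolated")
  out
}
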