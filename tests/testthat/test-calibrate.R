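test_that("pure tones have the specified amplitude, RMS, and sample count", {
  # integer-period tone: RMS = A / sqrt(2)
  w <- generate_tone(tone_spec(1000, amplitude = 0.5, duration = 1))
  expect_lte(max(abs(w$samples)), 0.5)
  expect_lt(abs(sqrt(mean(w$samples^2)) - 0.5 / sqrt(2)), 1e-3)

  # quarter-sample-rate tone hits the exact quadrature points
  w4 <- generate_tone(tone_spec(11025, amplitude = 1, duration = 4 / 44100))
  expect_equal(w4$samples, c(0, 1, 0, -1), tolerance = 1e-12)

  # 6 s at 44.1 kHz is exactly 6 * 44100 samples
  w6 <- generate_tone(tone_spec(5000, duration = 6))
  expect_identical(length(w6$samples), 264600L)

  expect_error(tone_spec(30000, sample_rate = 44100), "Nyquist")
  expect_error(tone_spec(1000, amplitude = 1.5), "amplitude")
})

test_that("white noise is scaled standard normal and seed-reproducible", {
  w <- generate_white_noise(duration = 6, amplitude = 0.2, seed = 12)
  n <- length(w$samples)
  expect_identical(n, 264600L)
  expect_lt(abs(sd(w$samples) - 0.2) / 0.2, 0.01)
  expect_lt(abs(mean(w$samples)), 4 * 0.2 / sqrt(n))
  expect_identical(generate_white_noise(duration = 6, amplitude = 0.2,
                                        seed = 12)$samples, w$samples)
})

test_that("the amplitude update rule evaluates its closed forms and self-inverts", {
  expect_equal(as.numeric(amplitude_update(0.4, 60, 60)), 0.4)  # fixed point
  expect_equal(as.numeric(amplitude_update(1.0, 70, 60)), 10^(-0.5),
               tolerance = 1e-12)
  expect_equal(as.numeric(amplitude_update(0.1, 54, 60)), 0.1 * 10^(0.3),
               tolerance = 1e-12)

  # swapping observed and target levels undoes the update
  a0 <- as.numeric(amplitude_update(0.25, 71, 63))
  expect_equal(as.numeric(amplitude_update(a0, 63, 71)), 0.25,
               tolerance = 1e-12)

  clipped <- amplitude_update(0.9, 50, 70)
  expect_equal(as.numeric(clipped), 1)
  expect_true(attr(clipped, "clipped"))
})

test_that("closed-loop calibration equalizes a nonflat noiseless chain", {
  # linear chain: the update rule is exact in one step
  flat <- synthetic_transducer(gain = 0)
  tab1 <- calibrate_frequencies(flat, target_level = 60, tolerance = 0.5)
  expect_true(all(tab1$iterations == 1))
  expect_true(all(abs(tab1$residual) < 1e-9))

  # +15 dB bump at 8 kHz: level equalized, amplitude dips at the bump
  bump <- synthetic_transducer(
    gain = function(f) 15 * exp(-(f - 8000)^2 / (2 * 1500^2)))
  tab2 <- calibrate_frequencies(bump, target_level = 60, tolerance = 1e-6,
                                single_step = TRUE)
  expect_true(all(abs(tab2$level - 60) < 1e-9))
  a8 <- tab2$amplitude[tab2$frequency == 8000]
  expect_lt(a8, tab2$amplitude[tab2$frequency == 7000])
  expect_lt(a8, tab2$amplitude[tab2$frequency == 9000])

  # measurement noise: still converges to tolerance within the budget
  noisy <- synthetic_transducer(gain = function(f) 5 * sin(f / 2000),
                                noise_sd = 0.05)
  tab3 <- calibrate_frequencies(noisy, target_level = 60, tolerance = 0.1,
                                max_iter = 10, seed = 31)
  expect_true(all(tab3$converged))
  expect_true(all(abs(tab3$residual) <= 0.1))

  # idempotence: restarting from a converged amplitude needs 0 updates
  for (k in c(1, 11, 21)) {
    re <- calibrate_frequencies(bump, freqs = tab2$frequency[k],
                                target_level = 60, tolerance = 0.5,
                                start_amplitude = tab2$amplitude[k])
    expect_identical(re$iterations, 0L)
  }
})

test_that("white-noise calibration averages per-anchor amplitudes", {
  # flat chain: all anchors agree, mean equals the single-tone amplitude
  flat <- synthetic_transducer(gain = 0)
  wn <- calibrate_white_noise(flat, target_level = 60)
  single <- as.numeric(amplitude_update(0.2, measure_spl(flat, 1000, 0.2), 60))
  expect_equal(as.numeric(wn), single, tolerance = 1e-12)

  # chain crafted so the anchor amplitudes are 0.1, 0.2, ..., 0.5
  targets <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  anchors <- c(1, 2, 5, 10, 20) * 1000
  crafted <- synthetic_transducer(
    gain = function(f) {
      a0 <- targets[match(f, anchors)]
      60 - 20 * log10(a0) - 94
    })
  expect_equal(as.numeric(calibrate_white_noise(crafted, target_level = 60)),
               0.3, tolerance = 1e-12)

  # tilted chain: the amplitude mean lies strictly inside the anchor range
  tilt <- synthetic_transducer(gain = function(f) 6 * log2(f / 1000))
  wn_t <- calibrate_white_noise(tilt, target_level = 60)
  a <- attr(wn_t, "anchors")
  expect_gt(as.numeric(wn_t), min(a))
  expect_lt(as.numeric(wn_t), max(a))
})

test_that("calibrated synthesis reaches any deliverable level and round-trips", {
  backend <- synthetic_transducer(gain = function(f) 8 * sin(f / 2500) - 3)
  tab <- calibrate_frequencies(backend, target_level = 60, tolerance = 1e-9,
                               single_step = TRUE)

  # L* = L0 returns the table amplitude exactly
  w60 <- synthesize_calibrated(tab, 5000, 60, duration = 0.01)
  expect_equal(attr(w60, "amplitudes"),
               tab$amplitude[tab$frequency == 5000], tolerance = 1e-12)

  # 20 dB down is a factor 10 in amplitude
  w40 <- synthesize_calibrated(tab, 5000, 40, duration = 0.01)
  expect_equal(attr(w40, "amplitudes"),
               tab$amplitude[tab$frequency == 5000] / 10, tolerance = 1e-12)

  # round trip: measuring any synthesized level returns the request
  for (lvl in c(45, 55, 60)) {
    amp <- attr(synthesize_calibrated(tab, 9000, lvl, duration = 0.01),
                "amplitudes")
    expect_lt(abs(measure_spl(backend, 9000, amp) - lvl), 1e-9)
  }

  # off-grid frequencies interpolate and are flagged
  wi <- synthesize_calibrated(tab, 4500, 55, duration = 0.01)
  expect_true(attr(wi, "interpolated"))

  # mixtures are additive with independent per-component amplitudes
  mix <- synthesize_calibrated(tab, c(3000, 7000), 50, duration = 0.01)
  s3 <- synthesize_calibrated(tab, 3000, 50, duration = 0.01)
  s7 <- synthesize_calibrated(tab, 7000, 50, duration = 0.01)
  expect_equal(mix$samples, s3$samples + s7$samples, tolerance = 1e-12)

  expect_error(synthesize_calibrated(tab, 5000, 130), "undeliverable")
  expect_error(synthesize_calibrated(tab, 500, 60), "outside")
})
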