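test_that("discretization produces event indicators and capped spike counts", {
  ev <- event_train(0.005)
  sp <- spike_train(c(0.011, 0.012), session_duration = 0.03)
  d <- discretize_session(0.03, ev, sp, delta = 0.01)
  expect_equal(d$x, c(1L, 0L, 0L))
  expect_equal(d$y, c(0L, 2L, 0L))  # 2 spikes in one bin, below the cap
  expect_equal(attr(d, "total_spikes"), 2)

  # excess spikes lump into the cap but the pre-cap total is conserved
  sp2 <- spike_train(rep(0.015, 7), session_duration = 0.03)
  d2 <- discretize_session(0.03, ev, sp2, delta = 0.01, count_cap = 3)
  expect_equal(d2$y[2], 3L)
  expect_equal(attr(d2, "total_spikes"), 7)

  expect_error(discretize_session(0.03, ev, sp, delta = 0.05), "delta")
})

test_that("plug-in MI matches brute-force table computation", {
  # hand-computable 2x2 table: joint counts ((40,10),(10,40)) over N = 100
  x <- rep(c(0L, 1L), each = 50)
  y <- c(rep(0L, 40), rep(1L, 10), rep(0L, 10), rep(1L, 40))
  joint <- matrix(c(40, 10, 10, 40), nrow = 2, byrow = TRUE)
  expect_equal(as.numeric(mutual_information(x, y)), oracle_mi_bits(joint),
               tolerance = 1e-12)

  # identity channel at p = 0.5 carries exactly one bit
  xb <- rep(c(0L, 1L), 50)
  expect_equal(as.numeric(mutual_information(xb, xb)), 1)

  # random joint tables: estimator equals the cell-by-cell oracle
  for (seed in 1:20) {
    set.seed(seed)
    n <- 500
    xr <- sample(0:2, n, replace = TRUE)
    yr <- sample(0:3, n, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
    joint <- unclass(table(xr, yr))
    expect_equal(as.numeric(mutual_information(xr, yr)),
                 oracle_mi_bits(joint), tolerance = 1e-12)
  }

  # independence: the mean plug-in MI over replicate sequences stays within
  # the first-order bias bound (a single draw has a chi-square tail)
  set.seed(99)
  n <- 100000
  bias <- 1 / (2 * n * log(2))  # (KxKy - Kx - Ky + 1) for 2x2
  reps <- replicate(20, as.numeric(
    mutual_information(rbinom(n, 1, 0.5), rbinom(n, 1, 0.3))))
  expect_lt(mean(reps), 3 * bias)

  expect_warning(mutual_information(rep(1L, 10), rep(0:1, 5)), "degenerate")
})

test_that("MI is symmetric at lag zero and never grows under category merging", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- rbinom(200, 1, 0.4)
    y <- rpois(200, 1 + x)
    expect_equal(as.numeric(mutual_information(x, y)),
                 as.numeric(mutual_information(y, x)), tolerance = 1e-12)
    merged <- pmin(y, 1)
    expect_lte(as.numeric(mutual_information(x, merged)),
               as.numeric(mutual_information(x, y)) + 1e-12)
  }

  # Miller-Madow subtracts the bias term and floors at zero
  set.seed(2)
  x <- rbinom(2000, 1, 0.5)
  y <- rbinom(2000, 1, 0.5)
  plain <- mutual_information(x, y)
  corr <- mutual_information(x, y, correction = "miller_madow")
  expect_equal(attr(corr, "raw"),
               as.numeric(plain) - 1 / (2 * 2000 * log(2)),
               tolerance = 1e-12)
  expect_gte(as.numeric(corr), 0)
})

test_that("lagged MI peaks at the evoked latency and degrades with event jitter", {
  sim <- simulate_experiment(simulation_config(seed = 17))
  mif <- mi_lag_function(sim$observed_events, sim$spikes, delta = 0.01,
                         lags = seq(-0.5, 0.5, by = 0.01))
  peak_lag <- mif$lag[which.max(mif$mi)]
  expect_lte(abs(peak_lag - 0.05), 0.01)  # within one bin of the latency

  # heavy jitter lowers the peak (averaged over sessions)
  peaks <- sapply(1:5, function(s) {
    noiseless <- simulate_experiment(simulation_config(seed = 200 + s))
    jittered <- simulate_experiment(
      simulation_config(seed = 200 + s, event_jitter_sd = 0.2))
    c(max(mi_lag_function(noiseless$observed_events, noiseless$spikes)$mi),
      max(mi_lag_function(jittered$observed_events, jittered$spikes)$mi))
  })
  expect_gt(mean(peaks[1, ]), mean(peaks[2, ]))
})

test_that("periodic events yield a secondary MI elevation one cycle after the response", {
  # short 0.5 s cycle: the absence of spikes between responses, and the
  # response to the NEXT event, both inform on event timing
  cfg <- simulation_config(seed = 55, session_duration = 120, n_events = 236,
                           event_interval = 0.5, evoked_latency_sd = 0.005,
                           evoked_spikes_per_event = 5, background_rate = 2)
  sim <- simulate_experiment(cfg)
  mif <- mi_lag_function(sim$observed_events, sim$spikes, delta = 0.01,
                         lags = seq(-0.3, 0.9, by = 0.01))
  mi_at <- function(l) mif$mi[which.min(abs(mif$lag - l))]
  secondary <- max(mi_at(0.54), mi_at(0.55), mi_at(0.56))
  expect_gt(secondary, median(mif$mi))
})

test_that("circular-shift shuffle null is calibrated and has power", {
  # independent trains: observed MI below the null's 95th percentile in
  # at least 90% of replicate sessions
  below <- 0
  for (rep in 1:50) {
    set.seed(300 + rep)
    dur <- 60
    ev <- event_train(sort(sample(seq(0.5, dur - 0.5, 0.25), 40)),
                      session_duration = dur)
    sp <- spike_train(sort(runif(300, 0, dur)), session_duration = dur)
    obs <- max(mi_lag_function(ev, sp, lags = 0)$mi)
    null <- shuffle_null(ev, sp, lag = 0, n_shuffles = 39, seed = 600 + rep)
    if (obs < quantile(null, 0.95)) below <- below + 1
  }
  expect_gte(below, 45)

  # locked trains: observed MI exceeds every one of 200 null draws
  sim <- simulate_experiment(simulation_config(seed = 77,
                                               session_duration = 120,
                                               n_events = 24))
  obs <- max(mi_lag_function(sim$observed_events, sim$spikes,
                             lags = 0.05)$mi)
  null <- shuffle_null(sim$observed_events, sim$spikes, lag = 0.05,
                       n_shuffles = 200, seed = 5)
  expect_gt(obs, max(null))

  # single shuffle with a fixed seed is reproducible
  n1 <- shuffle_null(sim$observed_events, sim$spikes, lag = 0.05,
                     n_shuffles = 1, seed = 9)
  n2 <- shuffle_null(sim$observed_events, sim$spikes, lag = 0.05,
                     n_shuffles = 1, seed = 9)
  expect_identical(n1, n2)
})
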