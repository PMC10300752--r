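test_that("identical seeds give bit-identical recordings", {
  a <- simulate_recording("loaded", 60, seed = 42)
  b <- simulate_recording("loaded", 60, seed = 42)
  expect_identical(a$channels, b$channels)
  c_ <- simulate_recording("loaded", 60, seed = 43)
  expect_false(identical(a$channels$O2Hb, c_$channels$O2Hb))
})

test_that("noise-free rapid breathing is a pure 25 breaths/min waveform", {
  p <- condition_params(rate_mean = 25, rate_jitter = 0,
                        amplitude_mean = 0.5, amplitude_jitter = 0,
                        drift_amplitude = 0, noise_sd = 0)
  rec <- simulate_recording("rapid_shallow", 300, params = p, seed = 1)
  t <- (seq_along(rec$channels$O2Hb) - 1) / 10
  f <- 25 / 60
  closed_form <- 0.5 * (sin(2 * pi * f * t) + 0.2 * sin(4 * pi * f * t))
  expect_equal(rec$channels$O2Hb, closed_form, tolerance = 1e-10)
  # independent periodogram oracle localises the spectral peak at 25/60 Hz
  sp <- stats::spec.pgram(stats::ts(rec$channels$O2Hb, frequency = 10),
                          taper = 0, detrend = TRUE, plot = FALSE)
  expect_equal(sp$freq[which.max(sp$spec)], f, tolerance = 0.01)
})

test_that("zero amplitude and noise leaves only the drift", {
  p <- condition_params(rate_mean = 14, rate_jitter = 0, amplitude_mean = 0,
                        amplitude_jitter = 0, drift_amplitude = 0.5,
                        drift_period = 60, noise_sd = 0)
  rec <- simulate_recording("baseline", 120, params = p, seed = 9)
  v <- rec$channels$O2Hb
  # a sinusoid of amplitude 0.5 and period 60 s: bounded and slow
  expect_lte(max(abs(v)), 0.5 + 1e-12)
  expect_gte(diff(range(v)), 0.9)
  sp <- stats::spec.pgram(stats::ts(v, frequency = 10), taper = 0,
                          detrend = FALSE, plot = FALSE)
  expect_lt(sp$freq[which.max(sp$spec)], 0.05)
})

test_that("HHb is anti-phase at reduced amplitude", {
  p <- condition_params(rate_mean = 14, rate_jitter = 0,
                        amplitude_mean = 1, amplitude_jitter = 0,
                        drift_amplitude = 0, noise_sd = 0)
  rec <- simulate_recording("baseline", 60, params = p, seed = 2)
  expect_equal(rec$channels$HHb, -0.4 * rec$channels$O2Hb,
               tolerance = 1e-10)
})

test_that("synthetic datasets are balanced, deterministic and subject-rich", {
  ws <- make_synthetic_dataset(100, seed = 5)
  expect_length(ws, 300)
  expect_identical(as.integer(table(ws$label)), c(100L, 100L, 100L))
  expect_identical(length(unique(ws$subject_id)), 21L)
  ws2 <- make_synthetic_dataset(100, seed = 5)
  expect_identical(ws$x, ws2$x)
  tiny <- make_synthetic_dataset(1, seed = 1)
  expect_length(tiny, 3)
})

test_that("per-window amplitude ordering is loaded > baseline > rapid", {
  ws <- make_synthetic_dataset(200, seed = 11)
  p2p <- apply(ws$x[, 1, ], 1, function(v) diff(range(v)))
  m <- tapply(p2p, ws$label, mean)
  expect_gt(m[["loaded"]], m[["baseline"]])
  expect_gt(m[["baseline"]], m[["rapid_shallow"]])
})

test_that("a dominant-frequency threshold separates rapid from the rest", {
  ws <- make_synthetic_dataset(300, seed = 13)
  f <- dominant_frequency(ws)
  # one cut between the slow classes (12-14 breaths/min) and 25 breaths/min
  cut <- mean(c(14, 25)) / 60
  pred_rapid <- f > cut
  truth_rapid <- ws$label == "rapid_shallow"
  expect_gt(mean(pred_rapid == truth_rapid), 0.95)
  # and the fitted three-class threshold baseline clears the same floor
  or <- periodogram_oracle(ws)
  expect_gt(accuracy_pct(predict(or, ws), ws$label), 95)
})

test_that("heavier sensor noise degrades threshold separability", {
  acc_at_noise <- vapply(c(0.1, 1.5, 4), function(ns) {
    params <- lapply(default_condition_params(), function(p) {
      p$noise_sd <- ns
      p
    })
    accs <- vapply(1:3, function(r) {
      ws <- make_synthetic_dataset(60, seed = 100 + r, params = params)
      or <- periodogram_oracle(ws)
      accuracy_pct(predict(or, ws), ws$label)
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  expect_gt(acc_at_noise[1], acc_at_noise[2])
  expect_gt(acc_at_noise[2], acc_at_noise[3])
})
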