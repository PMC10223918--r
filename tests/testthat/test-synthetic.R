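test_that("ssvep waveform is a deterministic decaying-harmonic sum", {
  w <- ssvep_waveform(13, 256, 512, c(1), phase = 0)
  tvec <- (0:511) / 256
  expect_equal(w, sin(2 * pi * 13 * tvec))
  expect_equal(w[1], 0)

  w3 <- ssvep_waveform(13, 256, 2048, c(1, 0.5, 0.25), phase = 0.3)
  pgram <- Mod(stats::fft(w3))^2
  f <- (seq_along(w3) - 1) * 256 / length(w3)
  pk <- function(f0) pgram[which.min(abs(f - f0))]
  expect_gt(pk(13), pk(26))
  expect_gt(pk(26), pk(39))

  expect_identical(ssvep_waveform(10, 128, 256, c(1, 0.5), 0.1),
                   ssvep_waveform(10, 128, 256, c(1, 0.5), 0.1))
  expect_error(ssvep_waveform(30, 128, 256, c(1, 0.5, 0.25)), "Nyquist")
})

test_that("background EEG has a 1/f spectrum with shared alpha", {
  expect_equal(background_eeg(3, 128, 128, amp = 0), matrix(0, 3, 128))
  b1 <- background_eeg(2, 512, 128, amp = 5, seed = 9)
  b2 <- background_eeg(2, 512, 128, amp = 5, seed = 9)
  expect_identical(b1, b2)
  expect_equal(apply(b1, 1, function(x) sqrt(mean(x^2))), c(5, 5),
               tolerance = 1e-6)

  # spectral slope of log power vs log frequency over 2-40 Hz near -1
  fs <- 128; n <- 60 * fs
  x <- background_eeg(1, n, fs, amp = 1, seed = 4)[1, ]
  pgram <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= 2 & f <= 40
  # average log-power in octave-ish bands to tame periodogram variance
  bands <- cut(log(f[keep]), 12)
  lp <- tapply(log(pgram[keep]), bands, mean)
  lf <- tapply(log(f[keep]), bands, mean)
  slope <- coef(lm(lp ~ lf))[2]
  expect_gt(slope, -1.5)
  expect_lt(slope, -0.5)
})

test_that("scenario validation rejects inconsistent settings", {
  expect_error(sim_scenario(harmonic_amps = c(1, 1)), "decreasing")
  expect_error(sim_scenario(crosstalk_gain = 2), "crosstalk")
  expect_error(sim_scenario(ssvep_amp = -1), "amplitudes")
  expect_error(sim_scenario(target_freqs = c(8, 30), fs = 128), "Nyquist")
})

test_that("simulated tensors have the recorded-study layout", {
  sim <- simulate_trials(sim_scenario(n_blocks = 12, seed = 1))
  expect_equal(dim(sim$tensor$data), c(32, 1024, 6, 12))
  expect_equal(sim$tensor$fs, 128)
  expect_equal(sim$tensor$target_freqs, c(8, 10, 12, 13, 14, 15))
  expect_equal(nrow(sim$truth), 72)
  expect_equal(sim$truth$target, rep(1:6, 12))
  expect_length(sim$montage$occipital_idx, 9)
  expect_length(sim$montage$nonoccipital_idx, 23)

  # reproducibility from the seed
  sim2 <- simulate_trials(sim_scenario(n_blocks = 12, seed = 1))
  expect_identical(sim$tensor$data, sim2$tensor$data)
})

test_that("the non-occipital mean tracks the occipital background", {
  sc <- sim_scenario(n_blocks = 1, ssvep_amp = 0, seed = 3)
  sim <- simulate_trials(sc)
  ep <- epochs(sim$tensor)[[1]]
  rs <- region_signals(ep, sim$montage)
  # occipital channels are crosstalk + sensor noise here; the reference
  # must correlate strongly with them for cancellation to work
  expect_gt(cor(rs$ref, rs$occ[1, ]), 0.5)
})

test_that("epochs of the same target are phase locked", {
  sc <- sim_scenario(n_blocks = 2, background_amp = 0, sensor_noise_amp = 0,
                     crosstalk_gain = 0)
  sim <- simulate_trials(sc)
  eps <- epochs(sim$tensor)
  a <- eps[[1]]$signal[32, ]  # occipital row, block 1, target 1
  b <- eps[[7]]$signal[32, ]  # same target, block 2
  cc <- stats::ccf(a, b, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("pipeline accuracy is non-decreasing in SSVEP amplitude", {
  cfg <- pipeline_config(rls_enabled = FALSE, window_length_s = 2,
                         selection_s = 2)
  acc <- vapply(c(0.5, 3, 12), function(a) {
    sim <- simulate_trials(sim_scenario(n_blocks = 17, epoch_s = 2,
                                        ssvep_amp = a, seed = 11))
    run_pipeline(sim$tensor, cfg)$accuracy
  }, numeric(1))
  # allow one inversion within binomial noise (102 epochs per level)
  se <- sqrt(0.25 / 102)
  expect_true(all(diff(acc) > -3 * se))
  expect_gt(acc[3], acc[1])
})
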