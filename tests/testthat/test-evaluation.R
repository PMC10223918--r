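test_that("block folds partition blocks without shuffling", {
  f6 <- block_kfold(6, 6)
  expect_equal(nrow(f6), 6)
  expect_true(all(lengths(f6$test_blocks) == 1))

  f12 <- block_kfold(12, 12)
  expect_equal(nrow(f12), 12)
  expect_equal(sort(unlist(f12$test_blocks)), 1:12)

  f3 <- block_kfold(12, 3)
  expect_true(all(lengths(f3$test_blocks) == 4))
  tests <- unlist(f3$test_blocks)
  expect_equal(sort(tests), 1:12)          # partition: union is everything
  expect_equal(anyDuplicated(tests), 0L)   # and pairwise disjoint
  for (i in seq_len(3)) {
    expect_equal(sort(c(f3$train_blocks[[i]], f3$test_blocks[[i]])), 1:12)
  }

  expect_error(block_kfold(6, 7), "exceeds")
  expect_error(block_kfold(12, 5), "divide")
})

test_that("accuracy is the exact fraction correct", {
  expect_equal(accuracy(1:4, 1:4), 1)
  expect_equal(accuracy(1:4, 4:1), 0)
  expect_equal(accuracy(c(1, 2, 3, 4), c(1, 2, 3, 9)), 0.75)
  expect_error(accuracy(1:3, 1:4), "mismatch")
  expect_error(accuracy(integer(0), integer(0)), "empty")
})

test_that("ITR identities and limits hold", {
  expect_equal(itr(6, 1 / 6, 10), 0, tolerance = 1e-12)
  expect_equal(itr(2, 1, 60), 1)
  # below-chance accuracies clamp to zero (reporting convention)
  expect_warning(v0 <- itr(2, 0, 60), "below chance")
  expect_equal(v0, 0)
  # frozen high-precision evaluation of the formula (mpmath, 30 digits)
  expect_equal(itr(40, 0.9441, 2), 141.465732172990, tolerance = 1e-9)
  expect_warning(v <- itr(6, 0.05, 2), "below chance")
  expect_equal(v, 0)
})

test_that("ITR is monotone in accuracy and in selection speed", {
  ps <- seq(1 / 6, 1, length.out = 25)
  vals <- vapply(ps, function(p) itr(6, p, 2), numeric(1))
  expect_true(all(diff(vals) > 0))
  ts <- c(1, 2, 4, 8)
  vt <- vapply(ts, function(T_s) itr(6, 0.9, T_s), numeric(1))
  expect_true(all(diff(vt) < 0))
})

test_that("narrowband SNR behaves like a periodogram bin ratio", {
  fs <- 128; n <- fs * 8
  tvec <- (seq_len(n) - 1) / fs
  pure <- sin(2 * pi * 12 * tvec)
  s <- narrowband_snr(pure, fs, 12)
  expect_gte(s, 60)
  expect_lte(s, 100)

  set.seed(41)
  noise <- rnorm(fs * 10)
  expect_lt(abs(narrowband_snr(noise, fs, 12)), 6)

  set.seed(42)
  nz <- rnorm(n)
  s1 <- narrowband_snr(pure + nz, fs, 12)
  s2 <- narrowband_snr(2 * pure + nz, fs, 12)
  expect_equal(s2 - s1, 6.02, tolerance = 1)

  expect_error(narrowband_snr(pure, fs, 70), "outside")
  expect_error(narrowband_snr(pure[1:64], fs, 12), "1 s")
})

test_that("run_pipeline is deterministic and perfect on noiseless data", {
  sc <- sim_scenario(n_blocks = 4, crosstalk_gain = 0, sensor_noise_amp = 0,
                     background_amp = 0, epoch_s = 4)
  sim <- simulate_trials(sc)
  cfg <- pipeline_config(window_length_s = 2, selection_s = 2)
  r1 <- run_pipeline(sim$tensor, cfg)
  expect_equal(r1$accuracy, 1)
  r2 <- run_pipeline(sim$tensor, cfg)
  expect_identical(tidy(r1), tidy(r2))

  # nothing to cancel: RLS on/off give identical predictions
  cfg_off <- pipeline_config(rls_enabled = FALSE, window_length_s = 2,
                             selection_s = 2)
  r3 <- run_pipeline(sim$tensor, cfg_off)
  expect_equal(tidy(r3)$pred, tidy(r1)$pred)

  g <- glance(r1)
  expect_equal(g$n_epochs, 24)
  expect_equal(g$accuracy, 1)
  expect_equal(g$itr_bits_per_min, itr(6, 1, 2))
})

test_that("reports echo the configuration and serialise to JSON/CSV", {
  sim <- simulate_trials(sim_scenario(n_blocks = 2, epoch_s = 2))
  cfg <- pipeline_config(window_length_s = 2, selection_s = 2, k_folds = 2)
  rep <- run_pipeline(sim$tensor, cfg)
  expect_equal(rep$config$selection_s, 2)
  expect_equal(rep$itr_bits_per_min,
               itr(6, rep$accuracy, 2), tolerance = 1e-12)
  expect_equal(rep$accuracy, mean(tidy(rep)$pred == tidy(rep)$target))

  js <- withr::local_tempfile(fileext = ".json")
  cs <- withr::local_tempfile(fileext = ".csv")
  write_eval_report(rep, js, cs)
  back <- jsonlite::read_json(js)
  expect_equal(back$accuracy, rep$accuracy, tolerance = 1e-12)
  expect_named(back$config, names(unclass(rep$config)), ignore.order = TRUE)
  csv <- utils::read.csv(cs)
  expect_equal(nrow(csv), nrow(tidy(rep)))
  expect_true(all(sprintf("rho_%g_hz", sim$tensor$target_freqs) %in%
                    names(csv)))
})

test_that("held-out predictions use no training-block data", {
  # the pipeline has no fitted training quantities: predictions for a block
  # must be unchanged when the training blocks' data are replaced
  sim <- simulate_trials(sim_scenario(n_blocks = 2, epoch_s = 2, seed = 5))
  cfg <- pipeline_config(window_length_s = 2, selection_s = 2)
  full <- run_pipeline(sim$tensor, cfg)
  tampered <- sim$tensor
  tampered$data[, , , 2] <- tampered$data[, , , 2] * 10 + 3
  half <- run_pipeline(tampered, cfg)
  b1 <- tidy(full)[tidy(full)$block == 1, c("target", "pred")]
  b1t <- tidy(half)[tidy(half)$block == 1, c("target", "pred")]
  expect_identical(b1, b1t)
})

test_that("config round-trips through YAML and JSON files", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "band: {low: 4, high: 30, order: 4}",
    "rls: {taps: 4, forgetting: 0.995, enabled: true}",
    "cca: {n_harmonics: 2}",
    "decimate: {factor: 8}",
    "selection_s: 2.5",
    "k_folds: 6"), yml)
  cfg <- read_pipeline_config(yml)
  expect_equal(cfg$band$high_hz, 30)
  expect_equal(cfg$rls$n_taps, 4L)
  expect_equal(cfg$rls$forgetting, 0.995)
  expect_equal(cfg$n_harmonics, 2L)
  expect_equal(cfg$decimate_factor, 8L)
  expect_equal(cfg$selection_s, 2.5)
  expect_equal(cfg$k_folds, 6)

  jsn <- withr::local_tempfile(fileext = ".json")
  writeLines('{"n_blocks": 3, "ssvep_amp": 1.5, "seed": 4}', jsn)
  sc <- read_sim_scenario(jsn)
  expect_equal(sc$n_blocks, 3L)
  expect_equal(sc$ssvep_amp, 1.5)
  jbad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"nonsense_key": 1}', jbad)
  expect_error(read_sim_scenario(jbad), "unknown scenario key")
})

test_that("autoplot methods return ggplot objects", {
  refs <- make_references(c(8, 13), 128, 256, 2)
  dec <- classify_epoch(refs$templates[[2]], refs)
  expect_s3_class(autoplot(dec), "ggplot")
  set.seed(44)
  tr <- rls_cancel(rnorm(300), rnorm(300), rls_params(2))
  expect_s3_class(autoplot(tr, fs = 128), "ggplot")
  sim <- simulate_trials(sim_scenario(n_blocks = 2, epoch_s = 2))
  rep <- run_pipeline(sim$tensor,
                      pipeline_config(window_length_s = 2, selection_s = 2))
  expect_s3_class(autoplot(rep), "ggplot")
})
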