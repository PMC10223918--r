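#' Block-wise K-fold splits
#'
#' Partitions the blocks of a recording into K folds without ever shuffling
#' epochs across blocks. When K equals the block count each fold holds out
#' exactly one block (leave-one-block-out); otherwise K must divide the
#' block count and folds are contiguous groups of blocks.
#'
#' @param n_blocks total number of blocks.
#' @param K number of folds; `K <= n_blocks` and `n_blocks %% K == 0`.
#' @return A tibble with one row per fold: `fold`, `train_blocks` and
#'   `test_blocks` (list-columns of block indices). Test sets partition the
#'   blocks.
#' @examples
#' block_kfold(6, 6)
#' @export
block_kfold <- function(n_blocks, K) {
  n_blocks <- as.integer(n_blocks)
  K <- as.integer(K)
  if (K > n_blocks) {
    stop(sprintf("K = %d exceeds block count %d", K, n_blocks), call. = FALSE)
  }
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (n_blocks %% K != 0L) {
    stop(sprintf("K = %d does not divide %d blocks", K, n_blocks),
         call. = FALSE)
  }
  per <- n_blocks %/% K
  test <- split(seq_len(n_blocks), rep(seq_len(K), each = per))
  tibble::tibble(
    fold = seq_len(K),
    train_blocks = lapply(test, function(ts) setdiff(seq_len(n_blocks), ts)),
    test_blocks = unname(test)
  )
}

#' Classification accuracy
#'
#' @param pred,truth equal-length label vectors.
#' @return The exact fraction of matching entries.
#' @export
accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop(sprintf("length mismatch: %d predictions, %d truths",
                 length(pred), length(truth)), call. = FALSE)
  }
  if (length(pred) == 0L) stop("empty label vectors", call. = FALSE)
  mean(pred == truth)
}

#' Information transfer rate (bits per minute)
#'
#' ITR = \[log2 M + P log2 P + (1 - P) log2((1 - P) / (M - 1))\] * 60 / T,
#' with the entropy terms taking their limits (0 log 0 = 0) at P = 0 or 1.
#' Below-chance accuracies (P < 1/M) give a negative bit rate; these are
#' clamped to 0 with a warning, matching BCI reporting convention.
#'
#' @param M number of selectable targets (>= 2).
#' @param P selection accuracy in \[0, 1\].
#' @param T_s seconds consumed per selection (gaze + decision time).
#' @return Bits per minute.
#' @examples
#' itr(2, 1, 60)   # 1 bit/min
#' itr(6, 0.9123, 2)
#' @export
itr <- function(M, P, T_s) {
  if (M < 2) stop("`M` must be >= 2", call. = FALSE)
  if (P < 0 || P > 1) stop("`P` must be in [0, 1]", call. = FALSE)
  if (T_s <= 0) stop("`T_s` must be positive", call. = FALSE)
  xlogx <- function(x) ifelse(x > 0, x * log2(x), 0)
  bits <- log2(M) + xlogx(P) + xlogx(1 - P) - (1 - P) * log2(M - 1)
  if (P < 1 / M) {
    warning(sprintf("accuracy %.3f below chance 1/%d; ITR clamped to 0", P, M),
            call. = FALSE)
    bits <- 0
  }
  bits * 60 / T_s
}

#' Narrowband SNR of a channel at a target frequency
#'
#' 10 log10 of the ratio between the periodogram power in the bin nearest
#' `f0` and the mean power of the neighbouring bins within +-1 Hz of `f0`
#' (the `f0` bin excluded). Capped at +-100 dB so a numerically silent
#' neighbourhood does not return infinity.
#'
#' @param channel numeric vector, at least one second of signal.
#' @param fs sampling rate in Hz.
#' @param f0 target frequency in Hz, below Nyquist.
#' @param neighborhood_hz half-width of the noise band (default 1 Hz).
#' @return SNR in dB.
#' @export
narrowband_snr <- function(channel, fs, f0, neighborhood_hz = 1) {
  n <- length(channel)
  if (n < fs) stop("need at least 1 s of signal", call. = FALSE)
  if (f0 <= 0 || f0 >= fs / 2) {
    stop(sprintf("f0 = %g Hz outside (0, %g)", f0, fs / 2), call. = FALSE)
  }
  pgram <- Mod(stats::fft(channel - mean(channel)))^2 / n
  freqs <- (seq_len(n) - 1L) * fs / n
  keep <- freqs <= fs / 2
  pgram <- pgram[keep]
  freqs <- freqs[keep]
  i0 <- which.min(abs(freqs - f0))
  nb <- which(abs(freqs - f0) <= neighborhood_hz & seq_along(freqs) != i0)
  if (length(nb) == 0L) stop("no neighbouring bins within the noise band; ",
                             "epoch too short for this resolution",
                             call. = FALSE)
  ratio <- pgram[i0] / mean(pgram[nb])
  db <- 10 * log10(ratio)
  if (!is.finite(db)) db <- ifelse(pgram[i0] > 0, 100, -100)
  min(max(db, -100), 100)
}

#' Run the full decoding pipeline with block-wise cross-validation
#'
#' For every fold and every epoch of its held-out blocks: band-pass filter,
#' decimate, split into occipital block and non-occipital mean reference,
#' optionally cancel the background by RLS, and classify by maximal
#' canonical correlation. No quantity is ever fitted on training blocks —
#' the CCA templates are data-independent and the RLS filter adapts within
#' the test epoch only — so block folds are a pure evaluation protocol and
#' the run is fully deterministic.
#'
#' @param t a [trial_tensor()].
#' @param config a [pipeline_config()].
#' @return An object of class `ssvep_eval`; see [tidy.ssvep_eval()] and
#'   [glance.ssvep_eval()].
#' @export
run_pipeline <- function(t, config = pipeline_config()) {
  stopifnot(inherits(t, "trial_tensor"), inherits(config, "pipeline_config"))
  nonocc <- config$nonocc_names %||%
    setdiff(t$channel_labels,
            t$channel_labels[tolower(t$channel_labels) %in%
                               tolower(config$occ_names)])
  m <- resolve_channel_sets(t$channel_labels, config$occ_names, nonocc)
  folds <- block_kfold(dim(t$data)[4], config$k_folds %||% dim(t$data)[4])
  eps <- epochs(t, config$window_start_s, config$window_length_s)
  fs_out <- t$fs / config$decimate_factor
  n_out <- length(eps[[1]]$signal[1, ]) / config$decimate_factor
  refs <- make_references(t$target_freqs, fs_out, n_out, config$n_harmonics)

  rows <- vector("list", length(eps))
  r <- 0L
  for (fi in seq_len(nrow(folds))) {
    test_blocks <- folds$test_blocks[[fi]]
    for (ep in eps) {
      if (!ep$block %in% test_blocks) next
      ep2 <- bandpass_filter(ep, config$band)
      ep2 <- decimate_epoch(ep2, config$decimate_factor)
      if (config$car_scope == "all") {
        ep2 <- common_average_reference(ep2)
      }
      reg <- region_signals(ep2, m)
      f_true <- t$target_freqs[ep$true_target]
      snr_before <- mean(apply(reg$occ, 1L, narrowband_snr, fs = fs_out,
                               f0 = f_true))
      occ <- reg$occ
      snr_after <- NA_real_
      if (config$rls_enabled) {
        occ <- enhance_epoch(reg$occ, reg$ref, config$rls)
        snr_after <- mean(apply(occ, 1L, narrowband_snr, fs = fs_out,
                                f0 = f_true))
      }
      dec <- classify_epoch(occ, refs, config$ridge)
      r <- r + 1L
      rows[[r]] <- tibble::tibble(
        fold = fi, block = ep$block, target = ep$true_target,
        freq = f_true, pred = dec$label, pred_freq = dec$freq,
        correct = dec$label == ep$true_target,
        snr_before_db = snr_before, snr_after_db = snr_after,
        rho = list(dec$rho))
    }
  }
  per_epoch <- dplyr::bind_rows(rows[seq_len(r)])
  acc <- accuracy(per_epoch$pred, per_epoch$target)
  report <- list(
    per_epoch = per_epoch,
    accuracy = acc,
    itr_bits_per_min = itr(length(t$target_freqs), acc, config$selection_s),
    snr_summary = tibble::tibble(
      condition = c("before_rls", "after_rls"),
      mean_snr_db = c(mean(per_epoch$snr_before_db),
                      mean(per_epoch$snr_after_db))),
    folds = folds,
    target_freqs = t$target_freqs,
    config = config
  )
  structure(report, class = "ssvep_eval")
}

#' @export
print.ssvep_eval <- function(x, ...) {
  cat(sprintf("<ssvep_eval> %d epochs over %d folds\n",
              nrow(x$per_epoch), nrow(x$folds)))
  cat(sprintf("  accuracy: %.4f   ITR: %.2f bits/min (T = %g s)\n",
              x$accuracy, x$itr_bits_per_min, x$config$selection_s))
  s <- x$snr_summary$mean_snr_db
  if (x$config$rls_enabled) {
    cat(sprintf("  mean SNR at true frequency: %.2f dB before, %.2f dB after RLS\n",
                s[1], s[2]))
  } else {
    cat(sprintf("  mean SNR at true frequency: %.2f dB (RLS disabled)\n", s[1]))
  }
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x an `ssvep_eval`.
#' @param ... unused.
#' @return The per-epoch tibble: fold, block, target, prediction,
#'   correctness, SNR before/after RLS (dB), and the per-frequency canonical
#'   correlations as a list-column.
#' @export
tidy.ssvep_eval <- function(x, ...) x$per_epoch

#' One-row summary of an evaluation report
#'
#' @param x an `ssvep_eval`.
#' @param ... unused.
#' @return Tibble with `n_epochs`, `accuracy`, `itr_bits_per_min`,
#'   `mean_snr_before_db`, `mean_snr_after_db`, `snr_gain_db`.
#' @export
glance.ssvep_eval <- function(x, ...) {
  s <- x$snr_summary$mean_snr_db
  tibble::tibble(
    n_epochs = nrow(x$per_epoch),
    accuracy = x$accuracy,
    itr_bits_per_min = x$itr_bits_per_min,
    mean_snr_before_db = s[1],
    mean_snr_after_db = s[2],
    snr_gain_db = s[2] - s[1]
  )
}

#' Write an evaluation report to JSON (and optionally per-epoch CSV)
#'
#' @param x an `ssvep_eval`.
#' @param path output JSON path.
#' @param csv_path optional CSV path for the per-epoch table (canonical
#'   correlations expanded to one column per candidate frequency).
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(x, path, csv_path = NULL) {
  stopifnot(inherits(x, "ssvep_eval"))
  cfg <- x$config
  cfg$band <- unclass(cfg$band)
  cfg$rls <- unclass(cfg$rls)
  out <- list(
    accuracy = x$accuracy,
    itr_bits_per_min = x$itr_bits_per_min,
    snr_summary = x$snr_summary,
    per_fold = lapply(split(x$per_epoch, x$per_epoch$fold), function(df) {
      list(fold = df$fold[1], predictions = df$pred, truths = df$target)
    }),
    config = unclass(cfg)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path)) {
    pe <- x$per_epoch
    rho <- do.call(rbind, pe$rho)
    colnames(rho) <- sprintf("rho_%g_hz", x$target_freqs %||%
                               seq_len(ncol(rho)))
    pe$rho <- NULL
    utils::write.csv(cbind(as.data.frame(pe), rho), csv_path,
                     row.names = FALSE)
  }
  invisible(path)
}
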