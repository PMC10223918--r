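#' Simulation scenario for synthetic SSVEP recordings
#'
#' Describes a synthetic study whose recordings have the statistical
#' structure the decoder assumes: phase-locked SSVEP with decaying harmonics
#' on the occipital channels, a shared volume-conducted background on all
#' channels, and independent sensor noise. Defaults emulate a 32-channel
#' 6-target protocol: 9 occipital plus 23 non-occipital channels, 8 s
#' epochs at 128 Hz, 12 blocks, so the full tensor has extents
#' (32, 1024, 6, 12).
#'
#' Amplitudes are on a microvolt scale typical of scalp EEG: 10 uV RMS
#' background, 3 uV SSVEP (a 0.3 signal-to-background ratio that degrades a
#' plain correlation decoder without flooring it), 1 uV sensor noise, and
#' unit crosstalk gain of the shared background into the occipital channels.
#'
#' @param n_occ,n_nonocc occipital / non-occipital channel counts.
#' @param fs sampling rate in Hz.
#' @param epoch_s epoch duration in seconds.
#' @param target_freqs stimulation frequencies in Hz, one per target.
#' @param n_blocks number of repeated blocks.
#' @param harmonic_amps strictly decreasing relative amplitudes of the
#'   fundamental and harmonics.
#' @param ssvep_amp SSVEP amplitude scale (uV).
#' @param background_amp RMS of the shared and channel-specific background
#'   (uV).
#' @param crosstalk_gain mixing coefficient in \[0, 1.5\] of the shared
#'   background into occipital channels (volume conduction).
#' @param sensor_noise_amp RMS of independent white sensor noise (uV).
#' @param phase per-target stimulus phase in radians; default quarter-cycle
#'   spacing `(0:(M-1)) * pi / 2`.
#' @param seed integer RNG seed; every epoch derives its own substream so
#'   individual epochs are reproducible.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_occ = 9, n_nonocc = 23, fs = 128, epoch_s = 8,
                         target_freqs = c(8, 10, 12, 13, 14, 15),
                         n_blocks = 12, harmonic_amps = c(1, 0.5, 0.25),
                         ssvep_amp = 3, background_amp = 10,
                         crosstalk_gain = 1, sensor_noise_amp = 1,
                         phase = NULL, seed = 1L) {
  if (any(diff(harmonic_amps) >= 0)) {
    stop("`harmonic_amps` must be strictly decreasing", call. = FALSE)
  }
  if (any(c(ssvep_amp, background_amp, sensor_noise_amp) < 0)) {
    stop("amplitudes must be >= 0", call. = FALSE)
  }
  if (crosstalk_gain < 0 || crosstalk_gain > 1.5) {
    stop("`crosstalk_gain` must be in [0, 1.5]", call. = FALSE)
  }
  if (max(target_freqs) * length(harmonic_amps) >= fs / 2) {
    stop("highest harmonic reaches Nyquist; lower `target_freqs`, drop ",
         "harmonics, or raise `fs`", call. = FALSE)
  }
  if (is.null(phase)) phase <- (seq_along(target_freqs) - 1) * pi / 2
  if (length(phase) == 1L) phase <- rep(phase, length(target_freqs))
  stopifnot(length(phase) == length(target_freqs))
  structure(
    list(n_occ = as.integer(n_occ), n_nonocc = as.integer(n_nonocc),
         fs = fs, epoch_s = epoch_s, target_freqs = as.numeric(target_freqs),
         n_blocks = as.integer(n_blocks), harmonic_amps = harmonic_amps,
         ssvep_amp = ssvep_amp, background_amp = background_amp,
         crosstalk_gain = crosstalk_gain, sensor_noise_amp = sensor_noise_amp,
         phase = phase, seed = as.integer(seed)),
    class = "sim_scenario")
}

#' Phase-locked SSVEP waveform
#'
#' Sum over harmonics h of `harmonic_amps[h] * sin(2 pi h f t + h * phase)`,
#' t = (0, ..., n - 1) / fs. Deterministic.
#'
#' @param f fundamental frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param n sample count.
#' @param harmonic_amps strictly decreasing per-harmonic amplitudes.
#' @param phase stimulus phase in radians.
#' @return Numeric vector of length `n`.
#' @export
ssvep_waveform <- function(f, fs, n, harmonic_amps = c(1, 0.5, 0.25),
                           phase = 0) {
  if (f * length(harmonic_amps) >= fs / 2) {
    stop("highest harmonic at or above Nyquist", call. = FALSE)
  }
  tvec <- (seq_len(n) - 1L) / fs
  out <- numeric(n)
  for (h in seq_along(harmonic_amps)) {
    out <- out + harmonic_amps[h] * sin(2 * pi * h * f * tvec + h * phase)
  }
  out
}

# 1/f-amplitude-shaped Gaussian noise via spectral shaping (power ~ 1/f)
pink_noise <- function(n, fs) {
  nfft <- n
  freqs <- seq(0, fs / 2, length.out = nfft %/% 2 + 1L)
  half <- complex(real = stats::rnorm(length(freqs)),
                  imaginary = stats::rnorm(length(freqs)))
  shape <- c(0, 1 / sqrt(freqs[-1]))  # amplitude ~ f^-0.5 => power ~ 1/f
  half <- half * shape
  spec <- c(half, Conj(rev(half[2:(length(half) - (1 - nfft %% 2))])))
  x <- Re(stats::fft(spec, inverse = TRUE))
  x / stats::sd(x)
}

# narrowband alpha component: white noise band-passed 8-12 Hz, unit RMS
alpha_noise <- function(n, fs) {
  bf <- signal::butter(2, c(8, 12) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  x / stats::sd(x)
}

#' Background EEG: 1/f noise plus a shared alpha rhythm
#'
#' Each channel is an independent 1/f-shaped ("pink") noise process (power
#' spectral exponent near 1) plus one 10 Hz-band alpha component common to
#' all channels — the classic narrowband confound overlapping the SSVEP
#' target band. Every channel is scaled to RMS `amp`.
#'
#' @param n_channels channel count.
#' @param n samples (at least one second, `n >= fs`).
#' @param fs sampling rate in Hz.
#' @param amp target RMS in uV; 0 gives an all-zero matrix.
#' @param seed RNG seed; output is reproducible.
#' @param alpha_weight relative weight of the shared alpha component
#'   (default 0.6).
#' @return `n_channels` x `n` numeric matrix.
#' @export
background_eeg <- function(n_channels, n, fs, amp, seed = 1L,
                           alpha_weight = 0.6) {
  if (n < fs) stop("background epochs must be at least 1 s long", call. = FALSE)
  if (amp == 0) return(matrix(0, n_channels, n))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  alpha <- alpha_noise(n, fs)
  out <- matrix(0, n_channels, n)
  for (ch in seq_len(n_channels)) {
    x <- pink_noise(n, fs) + alpha_weight * alpha
    out[ch, ] <- amp * x / sqrt(mean(x^2))
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate a trial tensor with known ground truth
#'
#' Builds a 4-D recording in the canonical (electrode, time, target, block)
#' layout. For the epoch of target frequency f: each occipital channel is
#' `ssvep_amp * ssvep_waveform(f) + crosstalk_gain * shared_background +
#' sensor noise`; each non-occipital channel is `shared_background +
#' independent background + sensor noise`. The shared background makes the
#' non-occipital mean a usable reference for adaptive cancellation. Channel
#' order is non-occipital channels first, then the occipital set.
#'
#' Each (target, block) epoch draws from its own counter-derived RNG
#' substream of `sc$seed`, so any single epoch is reproducible in isolation.
#'
#' @param sc a [sim_scenario()].
#' @return A list with `tensor` (a [trial_tensor()]), `truth` (tibble with
#'   `target`, `block`, `freq` per epoch in block-major order), and
#'   `montage` (the [resolve_channel_sets()] selection used).
#' @export
simulate_trials <- function(sc = sim_scenario()) {
  stopifnot(inherits(sc, "sim_scenario"))
  n <- as.integer(round(sc$epoch_s * sc$fs))
  n_ch <- sc$n_occ + sc$n_nonocc
  n_t <- length(sc$target_freqs)

  occ_pool <- occipital_9()
  occ_labels <- if (sc$n_occ <= length(occ_pool)) {
    occ_pool[seq_len(sc$n_occ)]
  } else {
    c(occ_pool, sprintf("Ox%d", seq_len(sc$n_occ - length(occ_pool))))
  }
  nonocc_pool <- setdiff(montage_1020_64(), occ_pool)
  nonocc_labels <- if (sc$n_nonocc <= length(nonocc_pool)) {
    nonocc_pool[seq_len(sc$n_nonocc)]
  } else {
    c(nonocc_pool, sprintf("Nx%d", seq_len(sc$n_nonocc - length(nonocc_pool))))
  }
  labels <- c(nonocc_labels, occ_labels)
  occ_rows <- sc$n_nonocc + seq_len(sc$n_occ)
  nonocc_rows <- seq_len(sc$n_nonocc)

  data <- array(0, c(n_ch, n, n_t, sc$n_blocks))
  epoch_counter <- 0L
  for (b in seq_len(sc$n_blocks)) {
    for (tg in seq_len(n_t)) {
      epoch_counter <- epoch_counter + 1L
      sub_seed <- (sc$seed + 99991L * epoch_counter) %% .Machine$integer.max
      f <- sc$target_freqs[tg]
      ssvep <- sc$ssvep_amp *
        ssvep_waveform(f, sc$fs, n, sc$harmonic_amps, sc$phase[tg])
      shared <- drop(background_eeg(1L, n, sc$fs, sc$background_amp,
                                    seed = sub_seed))
      indep <- background_eeg(sc$n_nonocc, n, sc$fs, sc$background_amp,
                              seed = sub_seed + 1L)
      old <- .Random.seed_save()
      set.seed(sub_seed + 2L)
      noise <- matrix(stats::rnorm(n_ch * n, sd = sc$sensor_noise_amp),
                      n_ch, n)
      .Random.seed_restore(old)
      ep <- matrix(0, n_ch, n)
      ep[nonocc_rows, ] <- sweep(indep, 2L, shared, "+")
      ep[occ_rows, ] <- matrix(rep(ssvep + sc$crosstalk_gain * shared,
                                   each = sc$n_occ), sc$n_occ, n)
      data[, , tg, b] <- ep + noise
    }
  }
  tensor <- trial_tensor(data, labels, sc$fs, sc$target_freqs)
  truth <- tidyr::expand_grid(block = seq_len(sc$n_blocks),
                              target = seq_len(n_t))
  truth$freq <- sc$target_freqs[truth$target]
  truth <- tibble::as_tibble(truth[, c("target", "block", "freq")])
  montage <- resolve_channel_sets(labels, occ_labels, nonocc_labels)
  list(tensor = tensor, truth = truth, montage = montage)
}
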