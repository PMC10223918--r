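#' Band-pass specification
#'
#' @param low_hz,high_hz pass-band edges in Hz, `0 < low < high`.
#' @param order overall filter order; even and at least 2. The band-pass is
#'   a Butterworth design of this order applied forward and backward
#'   (zero-phase), so the effective attenuation is doubled.
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(low_hz = 4, high_hz = 45, order = 4) {
  if (!is.numeric(low_hz) || !is.numeric(high_hz) || low_hz <= 0 ||
      high_hz <= low_hz) {
    stop("need 0 < low_hz < high_hz", call. = FALSE)
  }
  if (order < 2 || order %% 2 != 0) {
    stop("`order` must be an even integer >= 2", call. = FALSE)
  }
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order)),
            class = "band_spec")
}

#' The 4-30 Hz band reported for minimal preprocessing
#'
#' Preset band covering the fundamental and second harmonic of 8-15 Hz
#' stimuli. Note that it truncates third harmonics above 30 Hz; the default
#' [band_spec()] of 4-45 Hz keeps them.
#' @export
band_preset_narrow <- function() band_spec(4, 30, 4)

#' Zero-phase band-pass filter an epoch
#'
#' Removes each channel's mean (DC is outside any pass-band and would only
#' inject edge transients), then applies a Butterworth band-pass forward and
#' backward (`signal::filtfilt`) independently per channel, preserving SSVEP
#' phase locking. The first and last `max(3 * order, fs / low_hz)` samples
#' are still edge-affected; their count is recorded in the `edge_samples`
#' attribute rather than dropped.
#'
#' @param e an [epoch()].
#' @param band a [band_spec()].
#' @return The filtered epoch, same shape and metadata.
#' @export
bandpass_filter <- function(e, band = band_spec()) {
  stopifnot(inherits(e, "eeg_epoch"), inherits(band, "band_spec"))
  nyq <- e$fs / 2
  if (band$high_hz >= nyq) {
    stop(sprintf("band edge %g Hz >= Nyquist %g Hz", band$high_hz, nyq),
         call. = FALSE)
  }
  bf <- signal::butter(band$order / 2, c(band$low_hz, band$high_hz) / nyq,
                       type = "pass")
  sig <- t(apply(e$signal, 1L,
                 function(x) signal::filtfilt(bf, x - mean(x))))
  dim(sig) <- dim(e$signal)
  out <- epoch(sig, e$fs, e$true_target, e$block, e$channel_labels)
  attr(out, "edge_samples") <- as.integer(max(3L * band$order,
                                              ceiling(e$fs / band$low_hz)))
  out
}

#' Decimate an epoch
#'
#' Anti-alias low-pass filters (zero-phase Butterworth with cutoff at 0.8
#' times the new Nyquist frequency) and keeps every `factor`-th sample;
#' `fs` is updated accordingly.
#'
#' @param e an [epoch()].
#' @param factor positive integer dividing the sample count.
#' @return The decimated epoch at `fs / factor`.
#' @export
decimate_epoch <- function(e, factor) {
  stopifnot(inherits(e, "eeg_epoch"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("`factor` must be >= 1", call. = FALSE)
  if (factor == 1L) return(e)
  n <- ncol(e$signal)
  if (n %% factor != 0L) {
    stop(sprintf("factor %d does not divide sample count %d", factor, n),
         call. = FALSE)
  }
  new_fs <- e$fs / factor
  bf <- signal::butter(8, 0.8 * (new_fs / 2) / (e$fs / 2), type = "low")
  keep <- seq.int(1L, n, by = factor)
  sig <- t(apply(e$signal, 1L, function(x) signal::filtfilt(bf, x)[keep]))
  dim(sig) <- c(nrow(e$signal), length(keep))
  epoch(sig, new_fs, e$true_target, e$block, e$channel_labels)
}

#' Common average reference
#'
#' At every time point, subtracts the mean over the `over_idx` channels from
#' every channel. After referencing, the mean across the `over_idx` channels
#' is exactly zero at each sample, and any waveform common to all referenced
#' channels is removed.
#'
#' @param e an [epoch()].
#' @param over_idx non-empty integer vector of channel rows to average over
#'   (default: all channels, whole-head CAR).
#' @return The re-referenced epoch.
#' @export
common_average_reference <- function(e, over_idx = seq_len(nrow(e$signal))) {
  stopifnot(inherits(e, "eeg_epoch"))
  over_idx <- as.integer(over_idx)
  if (length(over_idx) == 0L) stop("`over_idx` must be non-empty", call. = FALSE)
  if (any(over_idx < 1L | over_idx > nrow(e$signal))) {
    stop("`over_idx` out of range", call. = FALSE)
  }
  m <- colMeans(e$signal[over_idx, , drop = FALSE])
  sig <- sweep(e$signal, 2L, m)
  epoch(sig, e$fs, e$true_target, e$block, e$channel_labels)
}

#' Split an epoch into occipital block and non-occipital mean reference
#'
#' The occipital submatrix carries the SSVEP plus crosstalk noise; the
#' sample-wise mean over the non-occipital channels is the background
#' reference fed to the adaptive canceller.
#'
#' @param e an [epoch()].
#' @param m a [resolve_channel_sets()] selection valid for `e`.
#' @return A list with `occ` (channels x samples matrix) and `ref`
#'   (numeric vector of length samples).
#' @export
region_signals <- function(e, m) {
  stopifnot(inherits(e, "eeg_epoch"), inherits(m, "montage_selection"))
  nc <- nrow(e$signal)
  if (any(c(m$occipital_idx, m$nonoccipital_idx) > nc)) {
    stop(sprintf("montage indexes beyond the epoch's %d channels", nc),
         call. = FALSE)
  }
  list(
    occ = e$signal[m$occipital_idx, , drop = FALSE],
    ref = colMeans(e$signal[m$nonoccipital_idx, , drop = FALSE])
  )
}
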