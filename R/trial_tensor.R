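#' Trial tensor: a 4-D EEG archive
#'
#' The unit of dataset exchange: a real-valued 4-D array in canonical axis
#' order (electrode, time point, target, block), in microvolts, together with
#' ordered 10-20 channel labels, the sampling rate and the stimulation
#' frequency assigned to each target.
#'
#' @param data numeric 4-D array, axes (electrode, time, target, block).
#' @param channel_labels character vector of 10-20 electrode names, one per
#'   row of the electrode axis.
#' @param fs sampling rate in Hz.
#' @param target_freqs numeric vector of stimulation frequencies (Hz), one
#'   per slice of the target axis.
#' @return An object of class `trial_tensor`.
#' @examples
#' a <- array(rnorm(2 * 64 * 3 * 2), c(2, 64, 3, 2))
#' trial_tensor(a, c("Oz", "Cz"), fs = 64, target_freqs = c(8, 10, 12))
#' @export
trial_tensor <- function(data, channel_labels, fs, target_freqs) {
  if (!is.array(data) || length(dim(data)) != 4L || !is.numeric(data)) {
    stop("`data` must be a numeric 4-D array (electrode, time, target, block)",
         call. = FALSE)
  }
  if (any(dim(data) < 1L)) stop("all tensor extents must be >= 1", call. = FALSE)
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != dim(data)[1L]) {
    stop(sprintf("electrode axis has extent %d but %d channel labels supplied",
                 dim(data)[1L], length(channel_labels)), call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  target_freqs <- as.numeric(target_freqs)
  if (length(target_freqs) != dim(data)[3L]) {
    stop(sprintf("target axis has extent %d but %d target frequencies supplied",
                 dim(data)[3L], length(target_freqs)), call. = FALSE)
  }
  if (anyNA(data) || any(!is.finite(data))) {
    stop("tensor data contain non-finite values", call. = FALSE)
  }
  structure(
    list(data = data, channel_labels = channel_labels, fs = as.numeric(fs),
         target_freqs = target_freqs),
    class = "trial_tensor"
  )
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<trial_tensor> %d channels x %d samples x %d targets x %d blocks @ %g Hz\n",
    d[1], d[2], d[3], d[4], x$fs))
  cat("  duration:", d[2] / x$fs, "s;  targets:",
      paste0(x$target_freqs, " Hz", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.trial_tensor <- function(x) dim(x$data)

#' Single-trial epoch
#'
#' One trial's channels-by-samples matrix with its metadata. Rows are
#' channels in the order of `channel_labels`; columns are time points.
#'
#' @param signal numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param true_target optional 1-based target index (NA if unknown).
#' @param block 1-based block index (NA if unknown).
#' @param channel_labels optional channel names.
#' @return An object of class `eeg_epoch`.
#' @export
epoch <- function(signal, fs, true_target = NA_integer_, block = NA_integer_,
                  channel_labels = NULL) {
  if (!is.matrix(signal) || !is.numeric(signal)) {
    stop("`signal` must be a numeric channels x samples matrix", call. = FALSE)
  }
  if (any(!is.finite(signal))) stop("epoch contains non-finite values", call. = FALSE)
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be positive", call. = FALSE)
  if (!is.null(channel_labels) && length(channel_labels) != nrow(signal)) {
    stop("channel_labels length must match channel count", call. = FALSE)
  }
  structure(
    list(signal = signal, fs = as.numeric(fs),
         true_target = as.integer(true_target), block = as.integer(block),
         channel_labels = channel_labels),
    class = "eeg_epoch"
  )
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> %d channels x %d samples @ %g Hz (target %s, block %s)\n",
              nrow(x$signal), ncol(x$signal), x$fs,
              ifelse(is.na(x$true_target), "?", x$true_target),
              ifelse(is.na(x$block), "?", x$block)))
  invisible(x)
}

#' Resolve occipital / non-occipital channel sets by name
#'
#' Maps two disjoint lists of 10-20 electrode names onto row indices of a
#' tensor's channel axis. Matching is case-insensitive; the order of the
#' requested names is preserved in the returned index lists.
#'
#' @param labels ordered character vector of channel labels (the montage).
#' @param occ_names names of the occipital (signal) channels.
#' @param nonocc_names names of the non-occipital (reference) channels.
#' @return An object of class `montage_selection`: a list with integer
#'   vectors `occipital_idx` and `nonoccipital_idx` (1-based).
#' @examples
#' resolve_channel_sets(c("Cz", "Oz"), "Oz", "Cz")
#' @export
resolve_channel_sets <- function(labels, occ_names, nonocc_names) {
  lab_lc <- tolower(labels)
  lookup <- function(nms, set) {
    idx <- match(tolower(nms), lab_lc)
    if (anyNA(idx)) {
      stop(sprintf("unknown %s channel name(s): %s", set,
                   paste(nms[is.na(idx)], collapse = ", ")), call. = FALSE)
    }
    as.integer(idx)
  }
  occ <- lookup(occ_names, "occipital")
  nonocc <- lookup(nonocc_names, "non-occipital")
  if (length(occ) == 0L || length(nonocc) == 0L) {
    stop("both channel sets must be non-empty", call. = FALSE)
  }
  overlap <- intersect(occ, nonocc)
  if (length(overlap) > 0L) {
    stop(sprintf("channel sets overlap: %s",
                 paste(labels[overlap], collapse = ", ")), call. = FALSE)
  }
  structure(list(occipital_idx = occ, nonoccipital_idx = nonocc),
            class = "montage_selection")
}

#' @export
print.montage_selection <- function(x, ...) {
  cat(sprintf("<montage_selection> %d occipital, %d non-occipital channels\n",
              length(x$occipital_idx), length(x$nonoccipital_idx)))
  invisible(x)
}

#' Extract epochs from a trial tensor
#'
#' Slices one epoch per (target, block) pair from a tensor, in block-major
#' order (block varies slowest), over a common time window.
#'
#' @param t a [trial_tensor()].
#' @param start_s window start in seconds (default 0).
#' @param length_s window length in seconds (default: full duration).
#' @return A list of [epoch()] objects of length targets x blocks, each
#'   carrying its true target and block index.
#' @examples
#' tt <- trial_tensor(array(0, c(2, 128, 2, 3)), c("Oz", "O1"), 128, c(8, 10))
#' length(epochs(tt))  # 6
#' @export
epochs <- function(t, start_s = 0, length_s = NULL) {
  stopifnot(inherits(t, "trial_tensor"))
  d <- dim(t$data)
  dur <- d[2] / t$fs
  if (is.null(length_s)) length_s <- dur - start_s
  if (start_s < 0 || start_s + length_s > dur + 1e-9) {
    stop(sprintf("window [%g, %g] s outside tensor duration %g s",
                 start_s, start_s + length_s, dur), call. = FALSE)
  }
  n_keep <- length_s * t$fs
  if (abs(n_keep - round(n_keep)) > 1e-6) {
    stop("length_s x fs must be an integer sample count", call. = FALSE)
  }
  n_keep <- as.integer(round(n_keep))
  i0 <- as.integer(round(start_s * t$fs))
  cols <- seq.int(i0 + 1L, i0 + n_keep)
  out <- vector("list", d[3] * d[4])
  k <- 1L
  for (b in seq_len(d[4])) {
    for (tg in seq_len(d[3])) {
      sig <- t$data[, cols, tg, b, drop = FALSE]
      dim(sig) <- c(d[1], n_keep)
      out[[k]] <- epoch(sig, t$fs, true_target = tg, block = b,
                        channel_labels = t$channel_labels)
      k <- k + 1L
    }
  }
  out
}

#' Packaged 64-channel 10-20 montage
#'
#' Returns the ordered channel labels of the standard 64-electrode extended
#' 10-20 layout used by public SSVEP benchmark recordings, from the table
#' shipped with the package. Used to supply labels when a data file omits
#' them.
#'
#' @return Character vector of 64 labels.
#' @export
montage_1020_64 <- function() {
  path <- system.file("extdata", "montage_1020_64.csv", package = "rlscca",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)$label
}

#' The nine-channel occipital recording set
#'
#' The parieto-occipital electrode set over visual cortex conventionally used
#' for SSVEP decoding: Pz, PO5, PO3, POz, PO4, PO6, O1, Oz, O2.
#'
#' @return Character vector of 9 labels.
#' @export
occipital_9 <- function() {
  c("Pz", "PO5", "PO3", "POz", "PO4", "PO6", "O1", "Oz", "O2")
}
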