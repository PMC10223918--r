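CANONICAL_AXES <- c("electrode", "time", "target", "block")

check_axis_order <- function(axis_order) {
  if (!setequal(axis_order, CANONICAL_AXES) || length(axis_order) != 4L) {
    stop("`axis_order` must be a permutation of ",
         paste(CANONICAL_AXES, collapse = ", "), call. = FALSE)
  }
  axis_order
}

guess_dialect <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, mat = "mat", h5 = "hdf5", hdf5 = "hdf5",
         stop("cannot infer dialect from extension '", ext,
              "'; pass `dialect` explicitly", call. = FALSE))
}

#' Load a 4-D trial tensor from a MAT or HDF5 file
#'
#' Reads the study's 4-D archive layout: a numeric array (electrode, time,
#' target, block) stored under `dataset` (default `"data"`), plus optional
#' `fs`, `channel_labels` and `target_freqs` entries. Metadata missing from
#' the file must be supplied via the corresponding arguments. Whatever axis
#' order the file declares, the returned tensor is normalised to the
#' canonical (electrode, time, target, block) order.
#'
#' @param path file path.
#' @param dialect `"mat"`, `"hdf5"`, or `"auto"` (infer from extension).
#' @param dataset name of the main array in the file.
#' @param channel_labels,fs,target_freqs fallbacks used when the file does
#'   not store them.
#' @param axis_order character permutation of
#'   `c("electrode", "time", "target", "block")` giving the on-disk axis
#'   order of the stored array.
#' @return A [trial_tensor()].
#' @export
load_trial_tensor <- function(path, dialect = c("auto", "mat", "hdf5"),
                              dataset = "data", channel_labels = NULL,
                              fs = NULL, target_freqs = NULL,
                              axis_order = CANONICAL_AXES) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") dialect <- guess_dialect(path)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  axis_order <- check_axis_order(axis_order)

  if (dialect == "mat") {
    vars <- read_mat5(path)
    if (is.null(vars[[dataset]])) {
      stop(sprintf("MAT file %s has no array named '%s' (found: %s)",
                   basename(path), dataset,
                   paste(names(vars), collapse = ", ")), call. = FALSE)
    }
    arr <- vars[[dataset]]
    file_fs <- if (!is.null(vars$fs)) as.numeric(vars$fs)[1] else NULL
    file_tf <- if (!is.null(vars$target_freqs)) as.numeric(vars$target_freqs) else NULL
    file_labels <- if (!is.null(vars$channel_labels) &&
                       is.character(vars$channel_labels)) {
      strsplit(vars$channel_labels, ";", fixed = TRUE)[[1]]
    } else NULL
  } else {
    contents <- rhdf5::h5ls(path)
    if (!dataset %in% contents$name) {
      stop(sprintf("HDF5 file %s has no dataset named '%s' (found: %s)",
                   basename(path), dataset,
                   paste(contents$name, collapse = ", ")), call. = FALSE)
    }
    has <- function(nm) nm %in% contents$name
    arr <- rhdf5::h5read(path, dataset)
    file_fs <- if (has("fs")) as.numeric(rhdf5::h5read(path, "fs"))[1] else NULL
    file_tf <- if (has("target_freqs")) {
      as.numeric(rhdf5::h5read(path, "target_freqs"))
    } else NULL
    file_labels <- if (has("channel_labels")) {
      as.character(rhdf5::h5read(path, "channel_labels"))
    } else NULL
  }

  if (!is.numeric(arr) || length(dim(arr)) != 4L) {
    stop(sprintf("dataset '%s' must be a numeric 4-D array, got extents [%s]",
                 dataset, paste(dim(arr), collapse = ", ")), call. = FALSE)
  }
  arr <- aperm(arr, match(CANONICAL_AXES, axis_order))

  fs <- file_fs %||% fs
  target_freqs <- file_tf %||% target_freqs
  channel_labels <- file_labels %||% channel_labels
  if (is.null(fs)) stop("file stores no `fs`; supply it", call. = FALSE)
  if (is.null(target_freqs)) {
    stop("file stores no `target_freqs`; supply them", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- if (dim(arr)[1] == 64L) montage_1020_64() else
      sprintf("ch%02d", seq_len(dim(arr)[1]))
  }
  trial_tensor(arr, channel_labels, fs, target_freqs)
}

#' Save a trial tensor to a MAT or HDF5 file
#'
#' Writes the data array under `dataset` together with `fs`,
#' `channel_labels` and `target_freqs`, so that [load_trial_tensor()]
#' reconstructs an equal tensor. The data array round-trips bit-exactly.
#'
#' @param t a [trial_tensor()].
#' @param path output path (overwritten if present).
#' @inheritParams load_trial_tensor
#' @return `path`, invisibly.
#' @export
save_trial_tensor <- function(t, path, dialect = c("auto", "mat", "hdf5"),
                              dataset = "data") {
  stopifnot(inherits(t, "trial_tensor"))
  dialect <- match.arg(dialect)
  if (dialect == "auto") dialect <- guess_dialect(path)
  if (dialect == "mat") {
    vars <- list(t$data, t$fs, t$target_freqs,
                 paste(t$channel_labels, collapse = ";"))
    names(vars) <- c(dataset, "fs", "target_freqs", "channel_labels")
    write_mat5(path, vars)
  } else {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(t$data, path, dataset)
    rhdf5::h5write(t$fs, path, "fs")
    rhdf5::h5write(t$target_freqs, path, "target_freqs")
    rhdf5::h5write(t$channel_labels, path, "channel_labels")
    rhdf5::h5closeAll()
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
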