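#' Sine/cosine harmonic reference templates
#'
#' For each candidate stimulation frequency f builds the CCA template
#' Y_f with 2 * n_harmonics rows: for harmonic h = 1..Nh, a
#' sin(2 pi h f t) row followed by a cos(2 pi h f t) row, with
#' t = (0, 1, ..., n_samples - 1) / fs.
#'
#' @param freqs candidate frequencies in Hz.
#' @param fs sampling rate in Hz.
#' @param n_samples template length in samples.
#' @param n_harmonics harmonic count Nh (>= 1); every harmonic of every
#'   frequency must lie below Nyquist, otherwise an error is raised (silent
#'   truncation would make the per-frequency scores incomparable).
#' @return An object of class `reference_set`: list with `freqs`,
#'   `n_harmonics`, `fs` and `templates` (one 2Nh x n matrix per frequency).
#' @examples
#' refs <- make_references(c(8, 10, 12), fs = 128, n_samples = 256)
#' @export
make_references <- function(freqs, fs, n_samples, n_harmonics = 3) {
  n_harmonics <- as.integer(n_harmonics)
  if (n_harmonics < 1L) stop("`n_harmonics` must be >= 1", call. = FALSE)
  if (length(freqs) < 1L || any(freqs <= 0)) {
    stop("`freqs` must be positive", call. = FALSE)
  }
  if (max(freqs) * n_harmonics >= fs / 2) {
    stop(sprintf("harmonic %d of %g Hz is at or above Nyquist (%g Hz)",
                 n_harmonics, max(freqs), fs / 2), call. = FALSE)
  }
  tvec <- (seq_len(n_samples) - 1L) / fs
  templates <- lapply(freqs, function(f) {
    rows <- lapply(seq_len(n_harmonics), function(h) {
      rbind(sin(2 * pi * h * f * tvec), cos(2 * pi * h * f * tvec))
    })
    do.call(rbind, rows)
  })
  structure(list(freqs = as.numeric(freqs), n_harmonics = n_harmonics,
                 fs = fs, templates = templates),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d frequencies (%s Hz), Nh = %d, %d samples @ %g Hz\n",
              length(x$freqs), paste(x$freqs, collapse = ", "),
              x$n_harmonics, ncol(x$templates[[1]]), x$fs))
  invisible(x)
}

# orthonormal basis of the centered row space; directions whose singular
# value falls below sqrt(tol) of the largest are treated as numerical noise
whitened_basis <- function(M, tol) {
  s <- svd(t(M))
  if (s$d[1] <= 0) {
    stop("rank-deficient input: all rows are constant", call. = FALSE)
  }
  keep <- s$d > s$d[1] * sqrt(tol)
  s$u[, keep, drop = FALSE]
}

#' Largest canonical correlation between two multichannel signals
#'
#' Centers each row, whitens each set by an SVD of its centered data matrix
#' (equivalent to Cxx^(-1/2), Cyy^(-1/2) on the auto-covariances, but
#' computed without forming them), and returns the largest singular value of
#' the cross-product of the two orthonormal bases — the maximum over
#' projection weight pairs of the correlation between the projected signals.
#' Row-space directions whose singular value is below `sqrt(ridge)` of the
#' largest are discarded as numerical noise, which keeps the whitening
#' stable with few samples and near-collinear channels.
#'
#' @param X p x n matrix (n samples in columns).
#' @param Y q x n matrix on the same samples.
#' @param ridge relative regularisation tolerance, default 1e-8.
#' @return The largest canonical correlation, clamped to \[0, 1\].
#' @export
canonical_correlation <- function(X, Y, ridge = 1e-8) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (!is.matrix(Y)) Y <- matrix(Y, nrow = 1L)
  n <- ncol(X)
  if (ncol(Y) != n) stop("X and Y must share the sample axis", call. = FALSE)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (n <= nrow(X) + nrow(Y)) {
    stop(sprintf("need n > p + q samples (n = %d, p = %d, q = %d)",
                 n, nrow(X), nrow(Y)), call. = FALSE)
  }
  Bx <- whitened_basis(X - rowMeans(X), ridge)
  By <- whitened_basis(Y - rowMeans(Y), ridge)
  rho <- svd(crossprod(Bx, By), nu = 0, nv = 0)$d[1]
  min(max(rho, 0), 1)
}

#' Classify an epoch by maximal canonical correlation
#'
#' Scores the (RLS-enhanced) occipital block against every harmonic
#' template and picks the frequency with the largest canonical correlation.
#' Exact ties resolve to the lowest frequency index and are reported via
#' `message()`.
#'
#' @param occ_block channels x samples matrix of occipital EEG.
#' @param refs a [make_references()] set with matching sample count.
#' @param ridge passed to [canonical_correlation()].
#' @return An object of class `ssvep_decision`: list with `label` (1-based
#'   index of the chosen frequency), `freq` (Hz), and `rho` (the per-
#'   frequency maximal canonical correlations).
#' @export
classify_epoch <- function(occ_block, refs, ridge = 1e-8) {
  stopifnot(inherits(refs, "reference_set"))
  if (!is.matrix(occ_block)) occ_block <- matrix(occ_block, nrow = 1L)
  if (ncol(occ_block) != ncol(refs$templates[[1]])) {
    stop(sprintf("epoch has %d samples but templates have %d",
                 ncol(occ_block), ncol(refs$templates[[1]])), call. = FALSE)
  }
  rho <- vapply(refs$templates,
                function(Yf) canonical_correlation(occ_block, Yf, ridge),
                numeric(1))
  label <- which.max(rho)
  if (sum(rho == rho[label]) > 1L) {
    message("tied canonical correlations; choosing lowest frequency index")
  }
  structure(list(label = label, freq = refs$freqs[label], rho = rho,
                 freqs = refs$freqs),
            class = "ssvep_decision")
}

#' @export
print.ssvep_decision <- function(x, ...) {
  cat(sprintf("<ssvep_decision> %g Hz (target %d); rho = %s\n", x$freq,
              x$label, paste(sprintf("%.3f", x$rho), collapse = ", ")))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a classification decision
#'
#' @param x an `ssvep_decision`.
#' @param ... unused.
#' @return A tibble with one row per candidate frequency: `freq`, `rho`,
#'   and `chosen`.
#' @export
tidy.ssvep_decision <- function(x, ...) {
  tibble::tibble(freq = x$freqs, rho = x$rho,
                 chosen = seq_along(x$rho) == x$label)
}
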