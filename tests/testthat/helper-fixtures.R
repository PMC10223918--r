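# shared fixtures, built in code

# tiny deterministic tensor: 2 channels, 3 targets, 2 blocks
tiny_tensor <- function(fs = 64, n = 128) {
  set.seed(7)
  a <- array(rnorm(2 * n * 3 * 2), c(2, n, 3, 2))
  trial_tensor(a, c("Oz", "Cz"), fs, c(8, 10, 12))
}

# batch exponentially-weighted regularised least squares on the same
# zero-padded sliding windows rls_cancel uses: the independent oracle for
# the recursion. With lambda = 1 this is ridge-regularised ordinary LS.
batch_rls_weights <- function(d, u, L, lambda = 1, delta = 0.01) {
  n <- length(d)
  upad <- c(numeric(L - 1), u)
  U <- vapply(seq_len(n), function(i) upad[(i + L - 1):i], numeric(L))
  U <- if (L == 1L) matrix(U, ncol = 1L) else t(U)
  wts <- lambda^(n - seq_len(n))
  A <- crossprod(U * wts, U) + delta * lambda^n * diag(L)
  solve(A, crossprod(U * wts, d))
}

# largest canonical correlation via explicit whitening + SVD, kept separate
# from the package implementation (dual-route check); rows must be centered
brute_force_cca <- function(X, Y) {
  n <- ncol(X)
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  isq <- function(C) {
    e <- eigen(C, symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(e$values), nrow(C)) %*% t(e$vectors)
  }
  M <- isq(tcrossprod(Xc) / (n - 1)) %*% (tcrossprod(Xc, Yc) / (n - 1)) %*%
    isq(tcrossprod(Yc) / (n - 1))
  svd(M)$d[1]
}

# dominant periodogram frequency of a vector
peak_freq <- function(x, fs) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2
  f <- (seq_len(n) - 1) * fs / n
  keep <- f > 0 & f <= fs / 2
  f[keep][which.max(p[keep])]
}
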