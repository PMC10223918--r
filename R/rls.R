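#' Recursive-least-squares canceller parameters
#'
#' @param n_taps filter order L: the number of most recent reference samples
#'   in the regression window u(n). Small values suffice for instantaneous
#'   volume-conduction mixing; default 8.
#' @param forgetting exponential forgetting factor lambda in (0, 1]. With
#'   lambda = 1 the recursion reproduces ordinary (growing-window) least
#'   squares exactly; default 0.999 keeps a long memory appropriate for
#'   short near-stationary epochs.
#' @param init_scale delta > 0: the inverse-correlation matrix is initialised
#'   to P(0) = I / delta with the weights at zero. Default 0.01.
#' @return An object of class `rls_params`.
#' @export
rls_params <- function(n_taps = 8, forgetting = 0.999, init_scale = 0.01) {
  n_taps <- as.integer(n_taps)
  if (is.na(n_taps) || n_taps < 1L) stop("`n_taps` must be >= 1", call. = FALSE)
  if (!is.numeric(forgetting) || forgetting <= 0 || forgetting > 1) {
    stop("`forgetting` must be in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(init_scale) || init_scale <= 0) {
    stop("`init_scale` must be > 0", call. = FALSE)
  }
  structure(list(n_taps = n_taps, forgetting = forgetting,
                 init_scale = init_scale),
            class = "rls_params")
}

#' Initialise RLS state
#'
#' Zero weight vector and P(0) = I / init_scale.
#'
#' @param params an [rls_params()].
#' @return An object of class `rls_state` with fields `w` (length-L weight
#'   vector), `P` (L x L inverse-correlation matrix), `n` (steps processed)
#'   and `params`.
#' @export
rls_init <- function(params = rls_params()) {
  stopifnot(inherits(params, "rls_params"))
  L <- params$n_taps
  structure(list(w = numeric(L), P = diag(L) / params$init_scale, n = 0L,
                 params = params),
            class = "rls_state")
}

#' One RLS update step
#'
#' Given the reference window u(n) and the desired sample d(n), computes the
#' a priori filter output y(n) = w(n-1)' u(n), the error e(n) = d(n) - y(n),
#' the gain k(n) = P(n-1) u(n) / (lambda + u(n)' P(n-1) u(n)), then updates
#' w(n) = w(n-1) + k(n) e(n) and
#' P(n) = (P(n-1) - k(n) u(n)' P(n-1)) / lambda. P is re-symmetrised each
#' step to suppress round-off drift. If any weight magnitude exceeds 1e6 the
#' state is reinitialised with a warning (finite-precision divergence guard).
#'
#' @param state an RLS state as returned by [rls_init()].
#' @param u_vec numeric reference window of length L.
#' @param d scalar desired sample.
#' @return A list with scalars `y` and `e` and the updated `state`.
#' @export
rls_step <- function(state, u_vec, d) {
  stopifnot(inherits(state, "rls_state"))
  L <- length(state$w)
  if (length(u_vec) != L) {
    stop(sprintf("reference window length %d but filter order is %d",
                 length(u_vec), L), call. = FALSE)
  }
  if (any(!is.finite(u_vec)) || !is.finite(d)) {
    stop("non-finite input to rls_step", call. = FALSE)
  }
  lam <- state$params$forgetting
  y <- sum(state$w * u_vec)
  e <- d - y
  Pu <- drop(state$P %*% u_vec)
  denom <- lam + sum(u_vec * Pu)
  k <- Pu / denom
  state$w <- state$w + k * e
  P <- (state$P - tcrossprod(k, Pu)) / lam
  state$P <- (P + t(P)) / 2
  state$n <- state$n + 1L
  if (any(abs(state$w) > 1e6)) {
    warning("RLS weights diverged (|w| > 1e6); reinitialising state",
            call. = FALSE)
    state <- rls_init(state$params)
  }
  list(y = y, e = e, state = state)
}

#' Adaptive noise cancellation of one channel
#'
#' Runs the RLS recursion over a whole epoch. The primary channel d carries
#' the occipital signal (SSVEP plus background crosstalk); the reference
#' channel u carries the non-occipital mean background. At each sample the
#' filter predicts the removable background component y(n) from the window
#' of the last L reference samples (zero-padded before sample L) and the
#' residual e(n) = d(n) - y(n) is the cleaned signal.
#'
#' @param d_channel numeric vector: primary (desired) channel.
#' @param u_channel numeric vector of the same length: reference channel.
#' @param params an [rls_params()].
#' @return An object of class `rls_trace`: list with `y` (noise estimate),
#'   `e` (cleaned signal), `d` (input copy), `J_hat` (running mean of
#'   squared error, the empirical cost), `w` (final weights), `fs` unset.
#' @export
rls_cancel <- function(d_channel, u_channel, params = rls_params()) {
  stopifnot(inherits(params, "rls_params"))
  n <- length(d_channel)
  if (length(u_channel) != n) {
    stop(sprintf("channel lengths differ: d has %d, u has %d samples",
                 n, length(u_channel)), call. = FALSE)
  }
  L <- params$n_taps
  if (n < L) stop("epoch shorter than the filter order", call. = FALSE)
  if (any(!is.finite(d_channel)) || any(!is.finite(u_channel))) {
    stop("non-finite input to rls_cancel", call. = FALSE)
  }
  lam <- params$forgetting
  w <- numeric(L)
  P <- diag(L) / params$init_scale
  upad <- c(numeric(L - 1L), u_channel)
  y <- numeric(n)
  e <- numeric(n)
  for (i in seq_len(n)) {
    u <- upad[(i + L - 1L):i]    # u(n), u(n-1), ..., u(n-L+1)
    yi <- sum(w * u)
    ei <- d_channel[i] - yi
    Pu <- drop(P %*% u)
    k <- Pu / (lam + sum(u * Pu))
    w <- w + k * ei
    P <- (P - tcrossprod(k, Pu)) / lam
    P <- (P + t(P)) / 2
    if (any(abs(w) > 1e6)) {
      warning("RLS weights diverged (|w| > 1e6); reinitialising state",
              call. = FALSE)
      w <- numeric(L)
      P <- diag(L) / params$init_scale
    }
    y[i] <- yi
    e[i] <- ei
  }
  structure(list(y = y, e = e, d = d_channel,
                 J_hat = cumsum(e^2) / seq_len(n), w = w, params = params),
            class = "rls_trace")
}

#' @export
print.rls_trace <- function(x, ...) {
  n <- length(x$e)
  cat(sprintf("<rls_trace> %d samples, L = %d, lambda = %g\n", n,
              x$params$n_taps, x$params$forgetting))
  cat(sprintf("  mean e^2: first quarter %.4g, last quarter %.4g\n",
              mean(x$e[seq_len(n %/% 4)]^2),
              mean(x$e[(n - n %/% 4 + 1L):n]^2)))
  invisible(x)
}

#' Enhance an occipital block by per-channel RLS cancellation
#'
#' Applies [rls_cancel()] independently to each occipital channel against
#' the shared non-occipital mean reference and returns the matrix of
#' residuals (cleaned SSVEP channels).
#'
#' @param occ_block channels x samples matrix.
#' @param ref_channel numeric vector of matching length.
#' @param params an [rls_params()].
#' @return Matrix of the same shape as `occ_block`.
#' @export
enhance_epoch <- function(occ_block, ref_channel, params = rls_params()) {
  stopifnot(is.matrix(occ_block))
  if (ncol(occ_block) != length(ref_channel)) {
    stop("occ_block and ref_channel sample counts differ", call. = FALSE)
  }
  out <- occ_block
  for (ch in seq_len(nrow(occ_block))) {
    out[ch, ] <- rls_cancel(occ_block[ch, ], ref_channel, params)$e
  }
  out
}
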