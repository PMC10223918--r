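test_that("initial state is zero weights and P = I / delta", {
  st <- rls_init(rls_params(n_taps = 4, init_scale = 0.01))
  expect_equal(st$w, rep(0, 4))
  expect_equal(st$P, 100 * diag(4))
  expect_equal(st$n, 0L)

  st1 <- rls_init(rls_params(n_taps = 1))
  expect_length(st1$w, 1)
  expect_equal(dim(st1$P), c(1L, 1L))

  expect_error(rls_params(init_scale = 0), "init_scale")
  expect_error(rls_params(forgetting = 0), "forgetting")
  expect_error(rls_params(n_taps = 0), "n_taps")
})

test_that("zero excitation leaves the weights untouched", {
  st <- rls_init(rls_params(n_taps = 3))
  out <- rls_step(st, c(0, 0, 0), d = 2.5)
  expect_equal(out$y, 0)
  expect_equal(out$e, 2.5)
  expect_equal(out$state$w, st$w)
  expect_error(rls_step(st, c(0, 0), 1), "order")
  expect_error(rls_step(st, c(0, 0, NA), 1), "non-finite")
})

test_that("scalar RLS converges to the true regression slope", {
  set.seed(21)
  u <- rnorm(60)
  st <- rls_init(rls_params(n_taps = 1, forgetting = 1, init_scale = 1e-6))
  for (i in seq_len(50)) st <- rls_step(st, u[i], 3 * u[i])$state
  expect_equal(unname(st$w), 3, tolerance = 1e-6)
})

test_that("with lambda = 1 the recursion equals batch least squares", {
  set.seed(22)
  for (L in c(1L, 3L, 8L)) {
    n <- 500L
    u <- rnorm(n)
    d <- as.numeric(stats::filter(u, seq_len(L) / L, sides = 1))
    d[is.na(d)] <- 0
    d <- d + 0.05 * rnorm(n)
    delta <- 0.01
    tr <- rls_cancel(d, u, rls_params(L, forgetting = 1, init_scale = delta))
    w_batch <- drop(batch_rls_weights(d, u, L, lambda = 1, delta = delta))
    expect_lt(max(abs(tr$w - w_batch)) / max(abs(w_batch)), 1e-8)
  }
})

test_that("exponential forgetting also matches the weighted batch solution", {
  set.seed(23)
  n <- 300L; L <- 4L
  u <- rnorm(n)
  d <- 2 * u - as.numeric(stats::filter(u, c(0, 0.5, 0, -0.2), sides = 1) |>
                            (\(x) { x[is.na(x)] <- 0; x })()) + 0.1 * rnorm(n)
  tr <- rls_cancel(d, u, rls_params(L, forgetting = 0.98, init_scale = 0.5))
  w_batch <- drop(batch_rls_weights(d, u, L, lambda = 0.98, delta = 0.5))
  expect_lt(max(abs(tr$w - w_batch)) / max(abs(w_batch)), 1e-8)
})

test_that("perfect cancellation when the primary equals the reference", {
  set.seed(24)
  u <- rnorm(1000)
  tr <- rls_cancel(u, u, rls_params(1, forgetting = 1, init_scale = 1e-4))
  tail_q <- tr$e[751:1000]
  expect_lt(mean(abs(tail_q)), 1e-3 * sqrt(mean(u^2)))
})

test_that("an uncorrelated reference removes (almost) nothing", {
  set.seed(25)
  d <- rnorm(2000)
  u <- rnorm(2000)
  tr <- rls_cancel(d, u, rls_params(4, forgetting = 0.999))
  half <- 1001:2000
  expect_lt(abs(mean(tr$e[half]^2) / mean(d[half]^2) - 1), 0.10)
})

test_that("a mixed-in reference is removed and the signal recovered", {
  set.seed(26)
  fs <- 128; n <- 1024
  s <- sin(2 * pi * 13 * (seq_len(n) - 1) / fs)
  u <- rnorm(n)
  d <- s + 0.8 * u
  tr <- rls_cancel(d, u, rls_params(1, forgetting = 0.999))
  half <- (n / 2 + 1):n
  expect_gt(cor(tr$e[half], s[half]), 0.95)
})

test_that("trace invariants: decomposition, cost decrease, scaling", {
  set.seed(27)
  n <- 800
  u <- rnorm(n)
  d <- 0.7 * u + 0.3 * rnorm(n)
  tr <- rls_cancel(d, u, rls_params(4))
  # d = y + e sample-wise
  expect_lt(max(abs(tr$d - (tr$y + tr$e))) / max(abs(tr$d)), 1e-12)
  # removable component: late cost below early cost
  q <- n %/% 4
  expect_lte(mean(tr$e[(n - q + 1):n]^2), mean(tr$e[1:q]^2))
  # scale equivariance: scaling d scales e exactly
  tr2 <- rls_cancel(5 * d, u, rls_params(4))
  expect_equal(tr2$e, 5 * tr$e, tolerance = 1e-12)
})

test_that("P stays symmetric through long runs", {
  set.seed(28)
  st <- rls_init(rls_params(n_taps = 5, forgetting = 0.99))
  u <- rnorm(400)
  for (i in 5:400) {
    st <- rls_step(st, u[i:(i - 4)], sum(u[i:(i - 4)]) + rnorm(1))$state
  }
  expect_lt(max(abs(st$P - t(st$P))) / max(abs(st$P)), 1e-8)
  expect_true(all(is.finite(st$w)))
})

test_that("enhance_epoch applies the canceller per channel", {
  set.seed(29)
  n <- 600
  ref <- rnorm(n)
  ch <- sin(2 * pi * 10 * seq_len(n) / 128) + 0.5 * ref
  block <- rbind(ch, ch)
  params <- rls_params(2)
  out <- enhance_epoch(block, ref, params)
  expect_identical(dim(out), dim(block))
  # identical input rows give identical cleaned rows
  expect_identical(out[1, ], out[2, ])
  # single row reduces to rls_cancel
  expect_equal(out[1, ], rls_cancel(ch, ref, params)$e)
  # zero reference: output equals input
  expect_equal(enhance_epoch(block, rep(0, n), params), block)
  expect_error(enhance_epoch(block, ref[-1], params), "differ")
})
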