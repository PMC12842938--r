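random_scan_inputs <- function(N, H, S, contraction = FALSE) {
  Abar <- array(if (contraction) runif(N * H * S, 0, 0.95)
                else rnorm(N * H * S, 0, 0.6), c(N, H, S))
  scan_inputs(Abar, array(rnorm(N * H * S, 0, 0.5), c(N, H, S)),
              matrix(rnorm(N * S), N, S))
}

test_that("scan oracle obeys closed-form special cases", {
  set.seed(1)
  N <- 6L; H <- 3L; S <- 2L
  inp <- random_scan_inputs(N, H, S)
  # memoryless limit: Abar = 0 makes y_t depend on step t only
  inp0 <- scan_inputs(array(0, c(N, H, S)), inp$Bu, inp$C)
  y0 <- scan_oracle(inp0)
  for (t in seq_len(N))
    expect_equal(y0[t, ], as.numeric(matrix(inp$Bu[t, , ], H, S) %*% inp$C[t, ]))
  # all-zero inputs give all-zero outputs
  z <- scan_inputs(inp$Abar, array(0, c(N, H, S)), inp$C)
  expect_equal(scan_oracle(z), matrix(0, N, H))
  # Abar = 1, input on first state coordinate, readout e1 -> cumulative sum
  u <- rnorm(N)
  Bu <- array(0, c(N, 1L, S)); Bu[, 1, 1] <- u
  C <- matrix(0, N, S); C[, 1] <- 1
  cum <- scan_oracle(scan_inputs(array(1, c(N, 1L, S)), Bu, C))
  expect_equal(as.numeric(cum), cumsum(u))
})

test_that("selective scan matches the sequential oracle on random instances", {
  set.seed(42)
  for (i in 1:200) {
    N <- sample(1:128, 1); H <- sample(1:32, 1); S <- sample(1:8, 1)
    inp <- random_scan_inputs(N, H, S)
    expect_lt(max(abs(selective_scan(inp) - scan_oracle(inp))), 1e-5)
  }
})

test_that("selective scan is single-step exact at N = 1", {
  set.seed(2)
  inp <- random_scan_inputs(1L, 4L, 3L)
  expect_equal(as.numeric(selective_scan(inp)),
               as.numeric(matrix(inp$Bu[1, , ], 4, 3) %*% inp$C[1, ]))
})

test_that("scan elementary-op count scales linearly in sequence length", {
  set.seed(3)
  counts <- vapply(c(64L, 128L), function(N) {
    inp <- random_scan_inputs(N, 8L, 4L)
    flop_counter_reset()
    selective_scan(inp)
    flop_counter_read()
  }, numeric(1))
  expect_lt(abs(counts[2] / counts[1] - 2), 0.2)
})

test_that("contraction keeps states bounded on long sequences", {
  set.seed(4)
  N <- 500L; H <- 4L; S <- 3L
  inp <- random_scan_inputs(N, H, S, contraction = TRUE)
  y <- selective_scan(inp)
  bound <- max(abs(inp$Bu)) / (1 - 0.95) * max(abs(inp$C)) * S
  expect_true(all(is.finite(y)))
  expect_lt(max(abs(y)), bound)
})

test_that("discretisation follows the zero-order-hold / Euler rules", {
  A <- matrix(-1, 2, 3)
  d <- discretize(A, c(log(2), log(2)), c(1, 2, 3))
  expect_equal(d$Abar, matrix(0.5, 2, 3))          # exp(-ln 2)
  expect_equal(d$Bbar, log(2) * rbind(c(1, 2, 3), c(1, 2, 3)))
  # A = 0 gives identity dynamics for any dt
  expect_equal(discretize(matrix(0, 2, 2), c(3, 7), c(1, 1))$Abar,
               matrix(1, 2, 2))
  # dt -> 0 approaches identity transition and vanishing input
  d0 <- discretize(A, c(1e-9, 1e-9), c(1, 1, 1))
  expect_equal(d0$Abar, matrix(1, 2, 3), tolerance = 1e-6)
  expect_lt(max(abs(d0$Bbar)), 1e-8)
  expect_error(discretize(A, c(0, 1), c(1, 1, 1)), "positive")
})

test_that("mamba block preserves shape, is deterministic, and is finite", {
  set.seed(5)
  p <- mamba_params(6L, hidden_dim = 12L, state_dim = 4L, conv_kernel = 3L)
  x <- matrix(rnorm(10 * 6), 10)
  y <- mamba_block(x, p)
  expect_equal(dim(y), c(10L, 6L))
  expect_true(all(is.finite(y)))
  expect_identical(y, mamba_block(x, p))
  expect_error(mamba_block(x * NA, p), "non-finite")
})

test_that("zeroed output projection reduces the block to the residual", {
  set.seed(6)
  p <- mamba_params(5L, hidden_dim = 8L, state_dim = 3L, conv_kernel = 2L)
  p$out_proj$W$val[] <- 0
  p$out_proj$b$val[] <- 0
  x <- matrix(rnorm(8 * 5), 8)
  expect_equal(mamba_block(x, p), x)
})

test_that("autodiff gradients of the mamba block match finite differences", {
  set.seed(7)
  p <- mamba_params(4L, hidden_dim = 6L, state_dim = 3L, conv_kernel = 2L)
  x0 <- matrix(rnorm(5 * 4), 5)
  target <- matrix(rnorm(5 * 4), 5)
  loss_of <- function(xv) sum(mamba_block(xv, p) * target)
  tp <- ad_tape <- dynfuse:::ad_tape()
  xn <- dynfuse:::ad_const(tp, x0)
  out <- mamba_block(xn, p, tape = tp)
  loss <- dynfuse:::ad_mean_all(tp, dynfuse:::ad_mul(tp, out,
            dynfuse:::ad_const(tp, target)))
  dynfuse:::ad_backward(tp, loss)
  g <- xn$grad * length(out$val)   # mean -> sum rescale
  eps <- 1e-5
  for (i in sample(length(x0), 8L)) {
    xp <- x0; xm <- x0
    xp[i] <- xp[i] + eps; xm[i] <- xm[i] - eps
    fd <- (loss_of(xp) - loss_of(xm)) / (2 * eps)
    expect_lt(abs(g[i] - fd) / max(1e-6, abs(fd)), 1e-3)
  }
})
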