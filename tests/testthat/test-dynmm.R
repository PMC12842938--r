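make_dynmm <- function(cfg = tiny_config(), seed = 30L) {
  set.seed(seed)
  dynmm_params(cfg, compress_seed = 99L)
}

test_that("light audio encoder pools to a fixed 512-d descriptor", {
  p <- make_dynmm()
  const5 <- matrix(1, 5, 8)
  const9 <- matrix(1, 9, 8)
  f5 <- light_audio_encode(const5, p)
  expect_equal(ncol(f5), 512L)
  # replicate-padded conv + mean pooling: constant input is length-invariant
  expect_equal(f5, light_audio_encode(const9, p), tolerance = 1e-12)
  p0 <- make_dynmm()
  p0$lae$conv_w$val[] <- 0; p0$lae$conv_b$val[] <- 0
  p0$lae$lin$W$val[] <- 0; p0$lae$lin$b$val[] <- 0
  expect_true(all(light_audio_encode(const5, p0) == 0))
})

test_that("path gate emits a 4-way distribution, deterministically in eval mode", {
  p <- make_dynmm()
  fa <- matrix(rnorm(512), 1)
  s <- path_gate_scores(fa, p)
  expect_length(s, 4L)
  expect_true(all(s > 0 & s < 1))
  expect_equal(sum(s), 1, tolerance = 1e-6)
  expect_identical(s, path_gate_scores(fa, p))
  p0 <- make_dynmm()
  p0$gate1$W$val[] <- 0; p0$gate1$b$val[] <- 0
  p0$gate2$W$val[] <- 0; p0$gate2$b$val[] <- 0
  expect_equal(path_gate_scores(fa, p0), rep(0.25, 4L))
})

test_that("threshold path selection reproduces the printed branch table", {
  expect_equal(select_path(c(0.05, 0.02, 0.92, 0.01)), 3L)
  expect_equal(select_path(c(0.05, 0.80, 0.10, 0.05)), 3L)
  expect_equal(select_path(c(0.45, 0.30, 0.15, 0.10)), 2L)
  expect_equal(select_path(c(0.30, 0.30, 0.20, 0.20)), 4L)
  expect_equal(select_path(c(0.95, 0.02, 0.02, 0.01)), 1L)
  expect_equal(select_path(c(0.01, 0.01, 0.03, 0.95)), 4L)
  expect_equal(select_path(c(0.02, 0.02, 0.80, 0.16)), 4L)  # bumped 3 -> 4
})

test_that("video compression is a fixed norm-preserving random projection", {
  expect_true(all(compress_video(matrix(0, 4, 16), seed = 5L) == 0))
  x <- matrix(rnorm(4 * 16), 4)
  expect_identical(compress_video(x, 5L), compress_video(x, 5L))
  expect_false(identical(compress_video(x, 5L), compress_video(x, 6L)))
  set.seed(31)
  n <- 10000L
  X <- matrix(rnorm(n * 16), n)
  Y <- compress_video(X, seed = 7L)
  expect_lt(abs(mean(rowSums(Y^2)) / mean(rowSums(X^2)) - 1), 0.1)
  expect_error(compress_video(x, 1L, out_dim = 20L), "exceeds")
})

test_that("expert E1 never reads the video stream", {
  p <- make_dynmm()
  xa <- matrix(rnorm(6 * 8), 6)
  h1 <- run_modality_expert(1L, xa, NULL, p)
  h1b <- run_modality_expert(1L, xa, matrix(rnorm(48), 6), p)
  expect_identical(h1, h1b)
  expect_error(run_modality_expert(2L, xa, NULL, p), "requires video")
  expect_error(run_modality_expert(5L, xa, NULL, p), "1..4")
})

test_that("analytic op counts strictly increase over the expert tiers", {
  p <- make_dynmm()
  xa <- matrix(rnorm(10 * 8), 10)
  xv <- matrix(rnorm(10 * 8), 10)
  counts <- vapply(1:4, function(k) {
    flop_counter_reset()
    run_modality_expert(k, xa, xv, p)
    flop_counter_read()
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("fusion cells execute only the selected operation", {
  cfg <- tiny_config()
  p <- make_dynmm(cfg)
  st <- list(a = matrix(rnorm(6 * 8), 6), v = matrix(rnorm(6 * 8), 6),
             h = matrix(rnorm(6 * 8), 6))
  # O1 is invariant to arbitrary video changes
  h1 <- fusion_cell_forward(1L, st, c(1, 0, 0, 0), p)
  st2 <- st; st2$v <- st2$v + 100
  expect_identical(h1, fusion_cell_forward(1L, st2, c(1, 0, 0, 0), p))
  # other ops do read video
  expect_false(identical(fusion_cell_forward(1L, st, 2L, p),
                         fusion_cell_forward(1L, st2, 2L, p)))
  expect_error(fusion_cell_forward(1L, st, c(0.5, 0.5, 0, 0), p), "one-hot")
  counts <- vapply(1:4, function(k) {
    flop_counter_reset()
    fusion_cell_forward(1L, st, k, p)
    flop_counter_read()
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("expected cost reproduces the printed tier arithmetic", {
  expect_equal(expected_cost(c(1, 0, 0, 0)), 0.6)
  expect_equal(expected_cost(c(0.25, 0.25, 0.25, 0.25)), 1.375)
  cm <- cost_model()
  n_units <- 4L
  pi1 <- matrix(rep(c(1, 0, 0, 0), n_units), n_units, byrow = TRUE)
  expect_equal(expected_cost(c(1, 0, 0, 0), pi1),
               0.6 + n_units * cm$op_cost[["O1"]])
  # shifting mass from E1 to E4 strictly increases the expert term
  expect_gt(expected_cost(c(0.5, 0, 0, 0.5)), expected_cost(c(0.9, 0, 0, 0.1)))
  expect_error(expected_cost(c(0.5, 0.2, 0.2, 0.2)), "sum to 1")
  expect_true(all(diff(cm$expert_cost) > 0) && all(diff(cm$op_cost) > 0))
})

test_that("forced audio-only forward never touches the video stream", {
  cfg <- tiny_config()
  p <- make_dynmm(cfg)
  xa <- matrix(rnorm(7 * 8), 7)
  xv <- matrix(rnorm(7 * 8), 7)
  out <- dynmm_forward(xa, xv, p, cfg, mode = "hard", force_path = 1L,
                       force_ops = 1L)
  out2 <- dynmm_forward(xa, xv + 100, p, cfg, mode = "hard", force_path = 1L,
                        force_ops = 1L)
  expect_identical(out$h, out2$h)
  out3 <- dynmm_forward(xa, NULL, p, cfg, mode = "hard", force_path = 1L,
                        force_ops = 1L)
  expect_identical(out$h, out3$h)
})

test_that("hard-mode forward equals direct invocation of the selected parts", {
  cfg <- tiny_config()
  p <- make_dynmm(cfg)
  xa <- matrix(rnorm(7 * 8), 7)
  xv <- matrix(rnorm(7 * 8), 7)
  out <- dynmm_forward(xa, xv, p, cfg, mode = "hard")
  h <- run_modality_expert(out$path$selected, xa, xv, p)
  for (j in seq_len(cfg$n_units)) {
    h <- fusion_cell_forward(j, list(a = xa, v = xv, h = h),
                             out$fusion$hard[j, ], p)
  }
  expect_identical(out$h, h)
  # eval-mode determinism
  out2 <- dynmm_forward(xa, xv, p, cfg, mode = "hard")
  expect_identical(out$h, out2$h)
  expect_identical(out$path, out2$path)
})

test_that("soft selections follow the gate distribution (uniform for a null gate)", {
  cfg <- tiny_config()
  p <- make_dynmm(cfg)
  p$gate1$W$val[] <- 0; p$gate1$b$val[] <- 0
  p$gate2$W$val[] <- 0; p$gate2$b$val[] <- 0
  xa <- matrix(rnorm(7 * 8), 7)
  xv <- matrix(rnorm(7 * 8), 7)
  set.seed(33)
  sel <- integer(400)
  for (i in seq_along(sel)) {
    out <- dynmm_forward(xa, xv, p, cfg, mode = "soft", tau = 1e3)
    sel[i] <- out$path$selected
  }
  freq <- tabulate(sel, 4L) / length(sel)
  expect_true(all(abs(freq - 0.25) < 0.08))
})
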