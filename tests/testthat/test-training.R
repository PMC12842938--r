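test_that("gumbel-softmax samples live on the simplex and calibrate to the logits", {
  set.seed(40)
  for (i in 1:20) {
    s <- gumbel_softmax_sample(rnorm(4), tau = runif(1, 0.1, 5))
    expect_equal(sum(s), 1, tolerance = 1e-6)
    expect_true(all(s >= 0))
  }
  # hard selection frequencies follow categorical(softmax(logits))
  logits <- log(c(0.7, 0.2, 0.1))
  set.seed(41)
  draws <- replicate(10000, which.max(gumbel_softmax_sample(logits, tau = 0.7,
                                                            hard = TRUE)))
  freq <- tabulate(draws, 3L) / 10000
  expect_true(all(abs(freq - c(0.7, 0.2, 0.1)) < 0.02))
  # tau -> 0 with fixed draws collapses the soft sample onto the argmax
  soft_lo <- gumbel_softmax_sample(logits, tau = 1e-4, seed = 9L)
  soft_hi <- gumbel_softmax_sample(logits, tau = 1, seed = 9L)
  expect_equal(max(soft_lo), 1, tolerance = 1e-9)
  expect_equal(which.max(soft_lo), which.max(soft_hi))
  # very high temperature flattens the soft sample toward uniform
  set.seed(42)
  soft_mean <- rowMeans(replicate(1000, gumbel_softmax_sample(logits, 1e3)))
  expect_true(all(abs(soft_mean - 1 / 3) < 0.05))
  expect_equal(gumbel_softmax_sample(0.3, tau = 1), 1)
  expect_error(gumbel_softmax_sample(logits, tau = 0), "tau")
})

test_that("temperature anneals geometrically between its endpoints", {
  sched <- list(tau_start = 5, tau_end = 0.1, epochs = 3L)
  expect_equal(anneal_temperature(0L, sched), 5)
  expect_equal(anneal_temperature(2L, sched), 0.1)
  expect_equal(anneal_temperature(1L, sched), sqrt(5 * 0.1))
  taus <- vapply(0:9, anneal_temperature,
                 schedule = list(tau_start = 5, tau_end = 0.1, epochs = 10L),
                 numeric(1))
  expect_true(all(diff(taus) < 0))
})

test_that("resource-aware loss is linear in lambda and exact at the tiers", {
  lb <- resource_aware_loss(0.5, c(1, 0, 0, 0), NULL, lambda = 0)
  expect_equal(lb$total, 0.5)
  cm <- cost_model()
  pi1 <- matrix(rep(c(1, 0, 0, 0), 4), 4, byrow = TRUE)
  lb1 <- resource_aware_loss(0.5, c(1, 0, 0, 0), pi1, lambda = 1)
  expect_equal(lb1$total, 0.5 + 0.6 + 4 * cm$op_cost[["O1"]])
  lb2 <- resource_aware_loss(0.5, c(1, 0, 0, 0), pi1, lambda = 2)
  expect_equal(lb2$total - 0.5, 2 * (lb1$total - 0.5))
  expect_equal(lb1$total, lb1$task_loss + lb1$lambda * lb1$cost_penalty,
               tolerance = 1e-12)
  expect_error(resource_aware_loss(0.5, c(1, 0, 0, 0), lambda = -1), "lambda")
})

test_that("focal loss reduces to cross-entropy and matches hand arithmetic", {
  set.seed(43)
  p <- matrix(runif(10, 0.05, 0.95))
  probs <- cbind(1 - p, p)
  y <- rbinom(10, 1, 0.5)
  ce <- -mean(log(probs[cbind(1:10, y + 1)]))
  expect_equal(focal_loss(probs, y, gamma = 0, alpha = 1), ce)
  expect_equal(focal_loss(matrix(c(0, 1), 1), 1L, gamma = 2), 0)
  expect_equal(focal_loss(matrix(c(0.5, 0.5), 1), 1L, gamma = 2, alpha = 1),
               -0.25 * log(0.5))
  expect_error(focal_loss(probs, y, gamma = -1), "gamma")
})

test_that("classifier head is a softmax over pooled features", {
  params <- list(cls = list(W = matrix(0, 8, 2), b = matrix(0, 1, 2)))
  h <- matrix(rnorm(6 * 8), 6)
  expect_equal(classify_head(h, params), c(0.5, 0.5))
  set.seed(44)
  params$cls$W <- matrix(rnorm(16), 8)
  p1 <- classify_head(h, params)
  expect_equal(sum(p1), 1, tolerance = 1e-9)
  params$cls$b <- matrix(c(3, 3), 1)   # common shift leaves softmax unchanged
  expect_equal(classify_head(h, params), p1)
})

test_that("straight-through estimation delivers gradients to the gates", {
  cfg <- tiny_config(channel_mode = "pooled")
  m <- tiny_model(cfg)
  s <- tiny_dataset(n = 1L, seed = 50L)[[1]]
  set.seed(51)
  tp <- dynfuse:::ad_tape()
  fw <- model_forward(m, s, mode = "soft", tau = 2, training = FALSE, tape = tp)
  loss <- dynfuse:::ad_ce_loss(tp, fw$logits, s$label + 1L)
  ec <- dynfuse:::expected_cost_node(tp, fw$path_probs_node,
                                     fw$fusion_probs_node, cost_model())
  dynfuse:::ad_backward(tp, dynfuse:::ad_add(tp, loss,
                        dynfuse:::ad_scale(tp, ec, 0.1)))
  g_gate <- m$params$dynmm$gate2$W$grad
  g_router <- m$params$mtem_a$router$W$grad
  expect_false(is.null(g_gate))
  expect_gt(max(abs(g_gate)), 0)
  expect_gt(max(abs(g_router)), 0)
})

test_that("training is deterministic and honours early stopping", {
  ds <- tiny_dataset(n = 24L, T = 32L, D = 2L, seed = 60L)
  cfg <- tiny_config(channel_mode = "pooled", max_epochs = 2L, patience = 1L,
                     batch_size = 8L, split_ratios = c(0.6, 0.2, 0.2))
  f1 <- train_model(ds, cfg)
  f2 <- train_model(ds, cfg)
  expect_equal(f1$history, f2$history)
  expect_identical(predict_model(f1, ds[1:4]), predict_model(f2, ds[1:4]))
  # patience 0: stops right after the first non-improving epoch
  cfg0 <- tiny_config(channel_mode = "pooled", max_epochs = 6L, patience = 0L,
                      batch_size = 8L, split_ratios = c(0.6, 0.2, 0.2))
  f3 <- train_model(ds, cfg0)
  h <- f3$history
  if (nrow(h) < 6L) {
    expect_gte(h$val_loss[nrow(h)], min(h$val_loss[-nrow(h)]))
  }
  expect_error(train_model(ds, tiny_config(split_ratios = c(1, 0, 0))),
               "non-empty")
})

test_that("checkpoints round-trip weights and predictions", {
  ds <- tiny_dataset(n = 20L, T = 32L, D = 2L, seed = 61L)
  cfg <- tiny_config(channel_mode = "pooled", max_epochs = 1L,
                     batch_size = 8L, split_ratios = c(0.6, 0.2, 0.2))
  fit <- train_model(ds, cfg)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  expect_identical(predict_model(back, ds[1:5]), predict_model(fit, ds[1:5]))
})

test_that("focal loss training runs with inverse-frequency weights", {
  ds <- tiny_dataset(n = 20L, T = 32L, D = 2L, seed = 62L, pos = 0.25)
  cfg <- tiny_config(channel_mode = "pooled", max_epochs = 1L, loss = "focal",
                     batch_size = 8L, split_ratios = c(0.6, 0.2, 0.2))
  fit <- train_model(ds, cfg)
  expect_equal(length(fit$alpha), 2L)
  expect_true(all(is.finite(fit$history$task_loss)))
  # minority (positive) class carries the larger weight
  expect_gt(fit$alpha[2], fit$alpha[1])
})
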