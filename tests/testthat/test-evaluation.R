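# brute-force confusion-matrix oracle used to cross-check compute_metrics
metrics_oracle <- function(y, p) {
  tab <- function(a, b) sum(y == a & p == b)
  tp <- tab(1, 1); fp <- tab(0, 1); fn <- tab(1, 0); tn <- tab(0, 0)
  pr <- function(num, den) if (den == 0) 0 else num / den
  prec1 <- pr(tp, tp + fp); rec1 <- pr(tp, tp + fn)
  prec0 <- pr(tn, tn + fn); rec0 <- pr(tn, tn + fp)
  f1 <- function(a, b) if (a + b == 0) 0 else 2 * a * b / (a + b)
  c(accuracy = (tp + tn) / length(y), precision = prec1, recall = rec1,
    f1 = f1(prec1, rec1), ua = (rec0 + rec1) / 2,
    wf1 = ((tn + fp) * f1(prec0, rec0) + (tp + fn) * f1(prec1, rec1)) /
      length(y))
}

test_that("six-metric report matches hand-checkable cases", {
  y <- c(1, 1, 0, 0)
  m_perfect <- compute_metrics(y, y)
  for (k in c("accuracy", "precision", "recall", "f1", "ua", "wf1"))
    expect_equal(m_perfect[[k]], 1)
  m <- compute_metrics(y, c(1, 0, 1, 0))
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 0.5)
  expect_equal(m$ua, 0.5)
  # constant-positive predictor: recall 1, precision = prevalence
  mc <- compute_metrics(c(1, 1, 1, 0, 0), rep(1, 5))
  expect_equal(mc$recall, 1)
  expect_equal(mc$precision, 0.6)
  # no positive predictions: precision 0 with a flag
  mz <- compute_metrics(c(1, 0), c(0, 0))
  expect_equal(mz$precision, 0)
  expect_true(mz$undefined_precision)
  expect_error(compute_metrics(integer(0), integer(0)), "non-empty")
  expect_error(compute_metrics(c(1, 2), c(1, 0)), "0/1")
})

test_that("metrics agree with the brute-force oracle on random cases", {
  set.seed(70)
  for (i in 1:1000) {
    n <- sample(2:40, 1)
    y <- rbinom(n, 1, runif(1, 0.1, 0.9))
    p <- rbinom(n, 1, runif(1, 0.1, 0.9))
    m <- compute_metrics(y, p)
    o <- metrics_oracle(y, p)
    expect_equal(c(m$accuracy, m$precision, m$recall, m$f1, m$ua, m$wf1),
                 unname(o))
  }
})

test_that("unweighted accuracy is invariant to class prevalence", {
  set.seed(71)
  # class-conditional predictor: recall 0.9 on positives, 0.7 on negatives
  draw <- function(n1, n0) {
    y <- c(rep(1, n1), rep(0, n0))
    p <- c(rbinom(n1, 1, 0.9), rbinom(n0, 1, 0.3))
    compute_metrics(y, p)$ua
  }
  ua_bal <- mean(replicate(200, draw(50, 50)))
  ua_imb <- mean(replicate(200, draw(90, 10)))
  expect_lt(abs(ua_bal - ua_imb), 0.02)
})

test_that("significance comparison reproduces the pooled t-test by hand", {
  a <- c(0.80, 0.82, 0.78, 0.81, 0.79)
  b <- c(0.70, 0.74, 0.69, 0.72, 0.75)
  rep <- significance_compare(a, b, n_comparisons = 7L)
  n1 <- 5; n2 <- 5
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p_hand <- 2 * pt(-abs(t_hand), n1 + n2 - 2)
  expect_equal(rep$t, t_hand, tolerance = 1e-10)
  expect_equal(rep$p_raw, p_hand, tolerance = 1e-10)
  expect_equal(rep$p_adjusted, min(1, p_hand * 7))
  expect_equal(rep$cohens_d, (mean(a) - mean(b)) / sqrt(sp2))
})

test_that("significance comparison handles degenerate and strong-effect cases", {
  x <- c(0.8, 0.81, 0.79, 0.8)
  rep0 <- significance_compare(x, x)
  expect_equal(rep0$mean_diff, 0)
  expect_equal(rep0$p_raw, 1)
  expect_error(significance_compare(rep(0.8, 4), rep(0.6, 4)), "pooled variance")
  set.seed(72)
  a <- rnorm(30, 0.8, 0.01); b <- rnorm(30, 0.6, 0.01)
  rep <- significance_compare(a, b)
  expect_lt(abs(rep$mean_diff - 0.2), 0.02)
  expect_gt(rep$cohens_d, 7)
})

test_that("robustness sweep reports exact degradation percentages", {
  cfg <- tiny_config(channel_mode = "pooled")
  m <- tiny_model(cfg)
  ds <- tiny_dataset(n = 10L, T = 32L, D = 2L, seed = 80L)
  base_only <- robustness_sweep(m, ds, list())
  expect_equal(nrow(base_only), 1L)
  specs <- list(perturbation_spec("gaussian_noise", sigma = 0, target = "both"),
                perturbation_spec("gaussian_noise", sigma = 2, target = "both"))
  tab <- robustness_sweep(m, ds, specs)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$degradation_acc[2], 0)       # sigma = 0 is the identity
  expect_equal(tab$degradation_acc[3],
               100 * (tab$accuracy[1] - tab$accuracy[3]) / tab$accuracy[1])
})

test_that("path distribution sums to one and prices forced routing", {
  cfg <- tiny_config(channel_mode = "pooled", n_units = 2L)
  m <- tiny_model(cfg)
  force_gate_to_path(m, 1L)
  ds <- tiny_dataset(n = 8L, T = 32L, D = 2L, seed = 81L)
  pd <- path_distribution(m, ds)
  expect_equal(sum(pd$fractions), 1)
  expect_equal(unname(pd$fractions), c(1, 0, 0, 0))
  # audio-only path: nominal expert cost exactly 0.6 plus the op tier costs
  expect_equal(pd$mean_nominal_cost - 0.6,
               mean(vapply(ds, function(s) {
                 fw <- model_forward(m, s, mode = "hard")
                 sum(fw$fusion$hard %*% cost_model()$op_cost)
               }, numeric(1))))
  expect_gt(pd$mean_analytic_flops, 0)
  expect_error(path_distribution(m, list()), "empty")
})

test_that("attention maps are row-stochastic and respect the band", {
  cfg <- tiny_config(channel_mode = "pooled")
  m <- tiny_model(cfg)
  s <- tiny_dataset(n = 1L, T = 32L, D = 2L, seed = 82L)[[1]]
  maps <- attention_maps(m, s)
  expect_gt(length(maps), 0L)
  for (mm in maps) expect_equal(rowSums(mm), rep(1, nrow(mm)), tolerance = 1e-6)
  lwt_maps <- maps[grepl("mtem", names(maps))]
  expect_gt(length(lwt_maps), 0L)
  hw <- tiny_config()$lwt_window %/% 2
  for (mm in lwt_maps) {
    N <- nrow(mm)
    outside <- abs(outer(seq_len(N), seq_len(N), "-")) > hw
    expect_true(all(mm[outside] == 0))
  }
  maps2 <- attention_maps(m, s)
  expect_identical(maps, maps2)
})
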