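fit_slopes <- function(samples, modality) {
  vapply(samples, function(s) {
    x <- s[[modality]]
    t <- seq_len(nrow(x))
    mean(apply(x, 2L, function(col) stats::cov(t, col) / stats::var(t)))
  }, numeric(1))
}

test_that("positive-class trend appears only in the informative modality", {
  ds <- tiny_dataset(n = 200L, T = 48L, D = 4L, seed = 3L,
                     informative = "audio", trend = 1.5, fluct = 0, noise = 0)
  y <- vapply(ds, function(s) s$label, integer(1))
  sa <- fit_slopes(ds, "audio")
  sv <- fit_slopes(ds, "video")
  # audio slopes separate the classes; video slopes do not
  expect_gt(mean(sa[y == 1]) - mean(sa[y == 0]), 0.005)
  expect_lt(abs(mean(sv[y == 1]) - mean(sv[y == 0])), 1e-8)
})

test_that("zero signal strengths give class-indistinguishable data", {
  ds <- tiny_dataset(n = 60L, seed = 9L, trend = 0, fluct = 0, noise = 0.5)
  y <- vapply(ds, function(s) s$label, integer(1))
  sa <- fit_slopes(ds, "audio")
  expect_gt(stats::t.test(sa[y == 1], sa[y == 0])$p.value, 0.01)
})

test_that("generation is a pure function of the config", {
  cfg <- generator_config(n_samples = 5L, T_a = 16L, D_a = 2L, T_v = 16L,
                          D_v = 2L, seed = 77L)
  expect_identical(generate_dataset(cfg), generate_dataset(cfg))
})

test_that("a trend-slope threshold separates the classes almost perfectly", {
  ds <- tiny_dataset(n = 200L, T = 48L, D = 4L, seed = 5L,
                     informative = "audio", trend = 1.5, fluct = 0,
                     noise = 0.3)
  y <- vapply(ds, function(s) s$label, integer(1))
  sa <- fit_slopes(ds, "audio")
  # brute-force threshold search (oracle classifier)
  accs <- vapply(sort(sa), function(th) mean((sa > th) == y), numeric(1))
  expect_gt(max(accs), 0.95)
})

test_that("gaussian noise injection targets the right modality with the right variance", {
  s <- random_sample(T = 100L, D = 100L, seed = 2L)
  expect_identical(inject_gaussian_noise(s, 0, "both", 1L), s)
  out <- inject_gaussian_noise(s, 1, "audio", seed = 3L)
  expect_identical(out$video, s$video)
  expect_false(identical(out$audio, s$audio))
  out2 <- inject_gaussian_noise(s, 0.5, "both", seed = 4L)
  d <- c(out2$audio - s$audio, out2$video - s$video)  # 2e4 entries
  expect_lt(abs(stats::var(d) - 0.25) / 0.25, 0.05)
  expect_error(inject_gaussian_noise(s, -1), ">= 0")
})

test_that("temporal disturbances follow their definitions", {
  s <- random_sample(T = 10L, D = 3L, seed = 4L)
  idsp <- function(kind, rate) perturbation_spec(kind, rate = rate,
                                                 target = "audio", seed = 8L)
  expect_identical(apply_temporal_disturbance(s, idsp("truncation", 0)), s)
  tr <- apply_temporal_disturbance(s, idsp("truncation", 0.5))
  expect_identical(tr$audio, s$audio[1:5, ])
  expect_identical(tr$video, s$video)
  sh <- apply_temporal_disturbance(s, idsp("shuffling", 1))
  expect_identical(sh$audio[order(sh$audio[, 1]), ],
                   s$audio[order(s$audio[, 1]), ])  # multiset equality
  mi <- apply_temporal_disturbance(s, idsp("missing_values", 0.3))
  expect_equal(sum(rowSums(mi$audio != 0) == 0), 3L)
  rs <- apply_temporal_disturbance(random_sample(T = 50L, seed = 5L),
                                   idsp("resampling", 0.5))
  expect_equal(dim(rs$audio), c(50L, 3L))          # length preserved
  expect_false(identical(rs$audio, random_sample(T = 50L, seed = 5L)$audio))
  expect_error(perturbation_spec("warp"), "unknown")
})

test_that("resampling removes high-frequency content but keeps slow trends", {
  T <- 64L
  slow <- sin(2 * pi * seq_len(T) / T)
  set.seed(99)
  fast <- rnorm(T)
  s <- multimodal_sample("r", cbind(slow), cbind(fast), 0L)
  out <- apply_temporal_disturbance(
    s, perturbation_spec("resampling", rate = 0.75, target = "both", seed = 1L))
  expect_lt(max(abs(out$audio - slow)), 0.25)       # slow component survives
  expect_lt(stats::var(out$video), 0.6 * stats::var(fast))  # fast attenuated
})

test_that("modality masking flags exactly the requested fraction of rows", {
  s <- random_sample(T = 100L, D = 4L, seed = 6L)
  expect_identical(mask_modality(s, "video", 0), s)
  mk <- mask_modality(s, "video", 0.3, seed = 2L)
  expect_equal(sum(mk$meta$missing_video), 30L)
  expect_true(all(mk$video[mk$meta$missing_video, ] == 0))
  expect_identical(mk$audio, s$audio)
  full <- mask_modality(s, "video", 1, seed = 2L)
  expect_true(all(full$meta$missing_video))
})

test_that("imputation restores masked rows per strategy", {
  s <- multimodal_sample("i", rbind(c(1, 3), c(3, 5), c(0, 0)),
                         matrix(0, 3, 2), 0L)
  s$meta$missing_audio <- c(FALSE, FALSE, TRUE)
  mean_out <- impute_missing(s, "mean")
  expect_equal(mean_out$audio[3, ], c(2, 4))
  expect_null(mean_out$meta$missing_audio)
  zero_out <- impute_missing(s, "zero")
  expect_equal(zero_out$audio[3, ], c(0, 0))
  clean <- random_sample(seed = 3L)
  expect_equal(impute_missing(clean, "mean"), clean)
  all_missing <- s
  all_missing$meta$missing_audio <- rep(TRUE, 3L)
  expect_error(impute_missing(all_missing, "mean"), "no observed rows")
})

test_that("perturbations never alter labels or sample ids", {
  s <- random_sample(seed = 12L, label = 1L, id = "keep")
  specs <- list(perturbation_spec("gaussian_noise", sigma = 1),
                perturbation_spec("truncation", rate = 0.5),
                perturbation_spec("shuffling", rate = 0.8),
                perturbation_spec("modality_mask", rate = 0.5, target = "video"))
  for (sp in specs) {
    out <- apply_perturbation(s, sp)
    expect_identical(out$sample_id, "keep")
    expect_identical(out$label, 1L)
  }
})
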