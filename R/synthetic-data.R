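#' Configuration for the synthetic two-modality sequence generator
#'
#' The generator emulates the shape of frame-level behavioural features used
#' in audio-visual depression screening: an audio stream of low-level
#' acoustic descriptors (default 25 channels, the usual LLD count) and a
#' video stream of facial geometry / action-unit style channels (default
#' 136, i.e. 68 landmark coordinate pairs). The class signal is planted at
#' two temporal scales so the long-range and short-range experts have
#' genuinely different structure to detect: positives carry a slow trend
#' (linear ramp plus a sinusoid with period about T) and burst-modulated
#' high-frequency fluctuations; negatives have zero trend slope and an
#' unmodulated fluctuation envelope.
#'
#' @param n_samples Number of samples to generate.
#' @param T_a,D_a Audio sequence length and channel count.
#' @param T_v,D_v Video sequence length and channel count.
#' @param trend_strength Amplitude of the slow trend planted in positives
#'   (>= 0, in feature z-score units).
#' @param fluctuation_strength Amplitude of the high-frequency component
#'   (>= 0); positives get a burst-modulated envelope, negatives a flat one.
#' @param informative_modality "audio", "video", or "both" — which stream
#'   carries the class signal; the other is pure noise.
#' @param noise_sd I.i.d. Gaussian noise added to every entry (>= 0).
#' @param positive_fraction Expected fraction of positive labels, in (0, 1).
#' @param seed Integer seed; generation is a pure function of the config.
#' @return A validated \code{generator_config} list.
#' @export
generator_config <- function(n_samples = 200L, T_a = 128L, D_a = 25L,
                             T_v = 128L, D_v = 136L,
                             trend_strength = 1, fluctuation_strength = 1,
                             informative_modality = c("both", "audio", "video"),
                             noise_sd = 0.5, positive_fraction = 0.5,
                             seed = 42L) {
  cfg <- list(n_samples = as.integer(n_samples),
              T_a = as.integer(T_a), D_a = as.integer(D_a),
              T_v = as.integer(T_v), D_v = as.integer(D_v),
              trend_strength = trend_strength,
              fluctuation_strength = fluctuation_strength,
              informative_modality = match.arg(informative_modality),
              noise_sd = noise_sd,
              positive_fraction = positive_fraction,
              seed = as.integer(seed))
  if (any(c(cfg$n_samples, cfg$T_a, cfg$D_a, cfg$T_v, cfg$D_v) < 1L))
    stop("generator_config: lengths and dims must be >= 1")
  if (cfg$trend_strength < 0 || cfg$fluctuation_strength < 0 || cfg$noise_sd < 0)
    stop("generator_config: strengths and noise_sd must be >= 0")
  if (!(cfg$positive_fraction > 0 && cfg$positive_fraction < 1))
    stop("generator_config: positive_fraction must lie in (0, 1)")
  class(cfg) <- "generator_config"
  cfg
}

# Class-dependent signal for one modality. Trend lives on a seeded subset of
# ceiling(D/4) channels; fluctuation on another seeded subset of the same
# size. Channel subsets and fluctuation periods are dataset-level (drawn once
# per generate_dataset call); phases and burst positions vary per sample.
modality_signal <- function(T, D, label, informative, plan, cfg) {
  x <- matrix(0, T, D)
  if (!informative) return(x)
  t01 <- if (T > 1) (seq_len(T) - 1) / (T - 1) else 0
  if (cfg$trend_strength > 0 && label == 1L) {
    for (c in plan$trend_channels) {
      phase <- stats::runif(1, 0, 2 * pi)
      x[, c] <- x[, c] + cfg$trend_strength * t01 +
        0.3 * cfg$trend_strength * sin(2 * pi * t01 + phase)
    }
  }
  if (cfg$fluctuation_strength > 0) {
    for (i in seq_along(plan$fluct_channels)) {
      c <- plan$fluct_channels[i]
      p <- plan$fluct_periods[i]
      phase <- stats::runif(1, 0, 2 * pi)
      env <- rep(1, T)
      if (label == 1L) {
        # bursts: three seeded windows of length ~T/8 with tripled amplitude
        wlen <- max(2L, T %/% 8L)
        for (b in seq_len(3L)) {
          st <- sample.int(max(1L, T - wlen + 1L), 1L)
          env[st:(st + wlen - 1L)] <- env[st:(st + wlen - 1L)] + 2
        }
      }
      x[, c] <- x[, c] + 0.5 * cfg$fluctuation_strength * env *
        sin(2 * pi * (seq_len(T) - 1) / p + phase)
    }
  }
  x
}

#' Generate a labelled synthetic multimodal dataset
#'
#' Deterministic given the config (including its seed). Labels are Bernoulli
#' draws with the configured positive fraction. The informative modality of a
#' positive sample carries a slow trend (slope proportional to
#' \code{trend_strength}) and burst-modulated high-frequency fluctuations;
#' negatives have neither (zero slope, flat fluctuation envelope). I.i.d.
#' Gaussian noise of sd \code{noise_sd} is added everywhere.
#'
#' @param cfg A [generator_config()].
#' @return List of [multimodal_sample()] objects.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    n_tr_a <- ceiling(cfg$D_a / 4); n_tr_v <- ceiling(cfg$D_v / 4)
    plan_a <- list(trend_channels = sample.int(cfg$D_a, n_tr_a),
                   fluct_channels = sample.int(cfg$D_a, n_tr_a),
                   fluct_periods = sample(4:8, n_tr_a, replace = TRUE))
    plan_v <- list(trend_channels = sample.int(cfg$D_v, n_tr_v),
                   fluct_channels = sample.int(cfg$D_v, n_tr_v),
                   fluct_periods = sample(4:8, n_tr_v, replace = TRUE))
    labels <- stats::rbinom(cfg$n_samples, 1L, cfg$positive_fraction)
    inf_a <- cfg$informative_modality %in% c("audio", "both")
    inf_v <- cfg$informative_modality %in% c("video", "both")
    lapply(seq_len(cfg$n_samples), function(i) {
      a <- modality_signal(cfg$T_a, cfg$D_a, labels[i], inf_a, plan_a, cfg) +
        matrix(stats::rnorm(cfg$T_a * cfg$D_a, 0, cfg$noise_sd), cfg$T_a)
      v <- modality_signal(cfg$T_v, cfg$D_v, labels[i], inf_v, plan_v, cfg) +
        matrix(stats::rnorm(cfg$T_v * cfg$D_v, 0, cfg$noise_sd), cfg$T_v)
      multimodal_sample(sprintf("s%04d", i), a, v, labels[i],
                        meta = list(source = "synthetic"))
    })
  })
}

#' Perturbation specification
#'
#' Describes one of the robustness-protocol perturbations: additive Gaussian
#' noise, temporal disturbances (truncation, resampling, shuffling, missing
#' values), or modality masking. \code{sigma} is only used by
#' \code{gaussian_noise}; \code{rate} by the others.
#'
#' @param kind One of "gaussian_noise", "truncation", "resampling",
#'   "shuffling", "missing_values", "modality_mask".
#' @param sigma Noise standard deviation (>= 0).
#' @param rate Disturbance / missing fraction in [0, 1].
#' @param target "audio", "video", or "both".
#' @param seed Integer seed for the seeded perturbations.
#' @return A \code{perturbation_spec} list.
#' @export
perturbation_spec <- function(kind, sigma = 0, rate = 0,
                              target = c("both", "audio", "video"),
                              seed = 1L) {
  kinds <- c("gaussian_noise", "truncation", "resampling", "shuffling",
             "missing_values", "modality_mask")
  if (!kind %in% kinds) stop("unknown perturbation kind: ", kind)
  if (sigma < 0) stop("sigma must be >= 0")
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  structure(list(kind = kind, sigma = sigma, rate = rate,
                 target = match.arg(target), seed = as.integer(seed)),
            class = "perturbation_spec")
}

targets_of <- function(target) {
  switch(target, audio = "audio", video = "video", both = c("audio", "video"))
}

#' Add i.i.d. Gaussian noise to a sample
#'
#' Entries of the targeted modality get independent N(0, sigma^2) additions;
#' the untargeted modality is returned bit-identical. sigma = 0 is the
#' identity.
#'
#' @param sample A [multimodal_sample()].
#' @param sigma Noise sd (>= 0).
#' @param target "audio", "video", or "both".
#' @param seed Integer seed.
#' @return The perturbed sample (label and id unchanged).
#' @export
inject_gaussian_noise <- function(sample, sigma, target = "both", seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(sample)
  with_seed(seed, {
    for (m in targets_of(target)) {
      sample[[m]] <- sample[[m]] +
        matrix(stats::rnorm(length(sample[[m]]), 0, sigma), nrow(sample[[m]]))
    }
  })
  sample
}

disturb_matrix <- function(x, kind, rate) {
  T <- nrow(x)
  switch(kind,
    truncation = {
      keep <- ceiling((1 - rate) * T)
      if (keep < 1L) keep <- 1L
      x[seq_len(keep), , drop = FALSE]
    },
    resampling = {
      m <- ceiling((1 - rate) * T)
      if (m < 2L) m <- 2L
      if (m >= T) return(x)
      # down-sample to m points then back to T by linear interpolation:
      # preserves length, loses high-frequency information
      tt <- seq_len(T)
      td <- seq(1, T, length.out = m)
      apply(x, 2L, function(col) {
        down <- stats::approx(tt, col, xout = td)$y
        stats::approx(td, down, xout = tt)$y
      })
    },
    shuffling = {
      k <- round(rate * T)
      if (k >= 2L) {
        idx <- sort(sample.int(T, k))
        x[idx, ] <- x[sample(idx), , drop = FALSE]
      }
      x
    },
    missing_values = {
      k <- round(rate * T)
      if (k >= 1L) x[sample.int(T, k), ] <- 0
      x
    },
    stop("unknown disturbance kind: ", kind))
}

#' Apply a temporal disturbance to a sample
#'
#' Implements the four disturbance protocols: \code{truncation} keeps the
#' first \code{ceiling((1-rate)*T)} rows; \code{resampling} linearly
#' interpolates down to that many rows and back to T (information loss at
#' preserved length); \code{shuffling} permutes a seeded fraction
#' \code{rate} of row indices among themselves; \code{missing_values} zeroes
#' a seeded fraction \code{rate} of rows.
#'
#' @param sample A [multimodal_sample()].
#' @param spec A [perturbation_spec()] with a temporal-disturbance kind.
#' @return The disturbed sample.
#' @export
apply_temporal_disturbance <- function(sample, spec) {
  stopifnot(inherits(spec, "perturbation_spec"))
  if (!spec$kind %in% c("truncation", "resampling", "shuffling", "missing_values"))
    stop("not a temporal disturbance kind: ", spec$kind)
  if (spec$rate == 0) return(sample)
  with_seed(spec$seed, {
    for (m in targets_of(spec$target)) {
      sample[[m]] <- disturb_matrix(sample[[m]], spec$kind, spec$rate)
    }
  })
  sample
}

#' Mask a fraction of a modality's time steps as missing
#'
#' A seeded fraction \code{rate} of the target modality's rows is replaced by
#' all-zero rows, and a logical missing mask is recorded in the sample's
#' \code{meta} (\code{missing_audio} / \code{missing_video}) for later
#' imputation. \code{rate = 1} marks the modality fully missing.
#'
#' @param sample A [multimodal_sample()].
#' @param target "audio" or "video" (or "both").
#' @param rate Fraction in [0, 1]; exactly \code{round(rate * T)} rows are
#'   flagged.
#' @param seed Integer seed.
#' @return The masked sample.
#' @export
mask_modality <- function(sample, target, rate, seed = 1L) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  if (rate == 0) return(sample)
  with_seed(seed, {
    for (m in targets_of(target)) {
      T <- nrow(sample[[m]])
      k <- round(rate * T)
      mask <- rep(FALSE, T)
      if (k >= 1L) mask[sample.int(T, k)] <- TRUE
      sample[[m]][mask, ] <- 0
      sample$meta[[paste0("missing_", m)]] <- mask
    }
  })
  sample
}

#' Impute masked time steps
#'
#' Requires the missing masks written by [mask_modality()]. \code{zero}
#' leaves flagged rows at zero; \code{mean} replaces each flagged row with
#' the per-feature mean over the modality's observed rows (an error when no
#' rows were observed). The mask is cleared afterwards.
#'
#' @param sample A masked [multimodal_sample()].
#' @param strategy "zero" or "mean".
#' @return The imputed sample with masks removed.
#' @export
impute_missing <- function(sample, strategy = c("zero", "mean")) {
  strategy <- match.arg(strategy)
  for (m in c("audio", "video")) {
    key <- paste0("missing_", m)
    mask <- sample$meta[[key]]
    if (is.null(mask) || !any(mask)) { sample$meta[[key]] <- NULL; next }
    if (strategy == "zero") {
      sample[[m]][mask, ] <- 0
    } else {
      if (all(mask))
        stop("mean imputation impossible for '", m, "': no observed rows")
      mu <- colMeans(sample[[m]][!mask, , drop = FALSE])
      sample[[m]][mask, ] <- matrix(mu, sum(mask), length(mu), byrow = TRUE)
    }
    sample$meta[[key]] <- NULL
  }
  sample
}

#' Apply any perturbation spec to a sample
#'
#' Dispatches on the spec's kind to [inject_gaussian_noise()],
#' [apply_temporal_disturbance()], or [mask_modality()].
#' @param sample A [multimodal_sample()].
#' @param spec A [perturbation_spec()].
#' @return The perturbed sample.
#' @export
apply_perturbation <- function(sample, spec) {
  stopifnot(inherits(spec, "perturbation_spec"))
  switch(spec$kind,
    gaussian_noise = inject_gaussian_noise(sample, spec$sigma, spec$target,
                                           spec$seed),
    modality_mask = mask_modality(sample, spec$target, spec$rate, spec$seed),
    apply_temporal_disturbance(sample, spec))
}
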