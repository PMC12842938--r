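#' Construct a labelled multimodal sample
#'
#' A sample pairs an audio feature sequence (\code{T_a x D_a}) with a video
#' feature sequence (\code{T_v x D_v}) and a binary label. Class 1 is the
#' positive ("depressed") class throughout the package; all precision/recall
#' style metrics are oriented accordingly. Rows are time steps, columns are
#' features.
#'
#' @param sample_id Character scalar, unique within a dataset.
#' @param audio Numeric matrix, time by feature.
#' @param video Numeric matrix, time by feature.
#' @param label Integer 0 or 1 (1 = positive class).
#' @param meta Named list of free-form metadata (source, sampling step,
#'   missing-row masks set by [mask_modality()]).
#' @return An object of class \code{multimodal_sample}.
#' @export
multimodal_sample <- function(sample_id, audio, video, label, meta = list()) {
  s <- structure(list(sample_id = as.character(sample_id),
                      audio = as.matrix(audio), video = as.matrix(video),
                      label = as.integer(label), meta = meta),
                 class = "multimodal_sample")
  validate_sample(s)
  s
}

#' Validate a multimodal sample's invariants
#'
#' Checks finiteness, non-empty sequences, and a 0/1 label.
#' @param s A \code{multimodal_sample}.
#' @return The sample, invisibly; errors describe the violated invariant and
#'   name the sample.
#' @export
validate_sample <- function(s) {
  id <- s$sample_id
  if (!is.matrix(s$audio) || !is.matrix(s$video))
    stop("sample '", id, "': audio and video must be matrices")
  if (nrow(s$audio) < 1L || nrow(s$video) < 1L)
    stop("sample '", id, "': each modality needs at least one time step")
  if (!all(is.finite(s$audio)) || !all(is.finite(s$video)))
    stop("sample '", id, "': non-finite feature values")
  if (!s$label %in% c(0L, 1L))
    stop("sample '", id, "': label must be 0 or 1")
  invisible(s)
}

#' @export
print.multimodal_sample <- function(x, ...) {
  cat(sprintf("<multimodal_sample %s> audio %dx%d, video %dx%d, label %d\n",
              x$sample_id, nrow(x$audio), ncol(x$audio),
              nrow(x$video), ncol(x$video), x$label))
  invisible(x)
}

sample_manifest_row <- function(s) {
  list(sample_id = s$sample_id,
       T_a = nrow(s$audio), D_a = ncol(s$audio),
       T_v = nrow(s$video), D_v = ncol(s$video),
       label = s$label)
}

#' Write a dataset of multimodal samples to a feature container
#'
#' Two on-disk layouts are supported. \code{format = "rds"} writes a single
#' binary tensor container (one file embedding every sample plus a manifest;
#' round-trips bit-exactly). \code{format = "csv"} writes an inspectable
#' directory with one CSV per modality per sample plus a \code{manifest.jsonl}
#' (one JSON object per sample; round-trips to printed precision).
#'
#' @param samples List of \code{multimodal_sample} objects (non-empty).
#' @param path Output file (rds) or directory (csv).
#' @param format "rds" (default) or "csv".
#' @return Invisibly, a manifest summary: sample count, per-sample shapes and
#'   the label histogram.
#' @export
write_feature_container <- function(samples, path, format = c("rds", "csv")) {
  format <- match.arg(format)
  if (length(samples) == 0L) stop("refusing to write an empty dataset")
  lapply(samples, validate_sample)
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sample_id in dataset")
  manifest <- lapply(samples, sample_manifest_row)
  labels <- vapply(samples, function(s) s$label, integer(1))
  hist <- c(`0` = sum(labels == 0L), `1` = sum(labels == 1L))
  summary <- list(n = length(samples), label_histogram = as.list(hist),
                  manifest = manifest)
  if (format == "rds") {
    saveRDS(list(container = "dynfuse-feature-container", version = 1L,
                 manifest = manifest, samples = samples), path)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    con <- file(file.path(path, "manifest.jsonl"), "w")
    on.exit(close(con))
    for (s in samples) {
      writeLines(jsonlite::toJSON(sample_manifest_row(s), auto_unbox = TRUE), con)
      data.table::fwrite(data.table::as.data.table(s$audio),
                         file.path(path, paste0(s$sample_id, "_audio.csv")))
      data.table::fwrite(data.table::as.data.table(s$video),
                         file.path(path, paste0(s$sample_id, "_video.csv")))
    }
  }
  invisible(summary)
}

#' Read a feature container written by [write_feature_container()]
#'
#' Samples are returned in manifest order. Every stored matrix is validated
#' against the manifest's recorded shape and label; a mismatch is an error
#' naming the offending sample.
#'
#' @param path An rds container file or a csv container directory.
#' @return List of \code{multimodal_sample} objects.
#' @export
read_feature_container <- function(path) {
  if (!file.exists(path)) stop("container not found: ", path)
  if (dir.exists(path)) {
    mf <- file.path(path, "manifest.jsonl")
    if (!file.exists(mf)) stop("container directory lacks manifest.jsonl: ", path)
    rows <- lapply(readLines(mf), jsonlite::fromJSON)
    samples <- lapply(rows, function(r) {
      a <- as.matrix(data.table::fread(
        file.path(path, paste0(r$sample_id, "_audio.csv"))))
      v <- as.matrix(data.table::fread(
        file.path(path, paste0(r$sample_id, "_video.csv"))))
      dimnames(a) <- NULL; dimnames(v) <- NULL
      check_against_manifest(r, a, v)
      multimodal_sample(r$sample_id, a, v, r$label)
    })
    return(samples)
  }
  obj <- readRDS(path)
  if (!identical(obj$container, "dynfuse-feature-container"))
    stop("not a dynfuse feature container: ", path)
  for (i in seq_along(obj$manifest)) {
    r <- obj$manifest[[i]]
    s <- obj$samples[[i]]
    check_against_manifest(r, s$audio, s$video)
    if (!identical(as.integer(r$label), s$label))
      stop("sample '", r$sample_id, "': stored label disagrees with manifest")
  }
  obj$samples
}

check_against_manifest <- function(r, a, v) {
  if (nrow(a) != r$T_a || ncol(a) != r$D_a)
    stop("sample '", r$sample_id, "': audio shape ", nrow(a), "x", ncol(a),
         " does not match manifest ", r$T_a, "x", r$D_a)
  if (nrow(v) != r$T_v || ncol(v) != r$D_v)
    stop("sample '", r$sample_id, "': video shape ", nrow(v), "x", ncol(v),
         " does not match manifest ", r$T_v, "x", r$D_v)
  invisible(NULL)
}

#' Split sample ids into train/validation/test sets
#'
#' A pure function of the sample ids, the ratios and the seed. Ids are
#' shuffled deterministically, then apportioned by the largest-remainder rule
#' so per-split counts are the integer apportionment of the ratios (e.g. 10
#' samples at 7:1:2 give sizes 7, 1, 2). Splitting is by sample id only, so
#' subject-level separation holds whenever ids identify subjects.
#'
#' @param samples List of samples, or a character vector of sample ids.
#' @param ratios Numeric length-3 (train, val, test), non-negative, summing
#'   to 1 within 1e-9.
#' @param seed Integer seed.
#' @return A \code{dataset_split}: list with \code{train}, \code{val},
#'   \code{test} id vectors plus the ratios and seed.
#' @export
make_split <- function(samples, ratios = c(0.7, 0.1, 0.2), seed = 42L) {
  ids <- if (is.character(samples)) samples
         else vapply(samples, function(s) s$sample_id, character(1))
  if (length(ratios) != 3L || any(ratios < 0))
    stop("ratios must be three non-negative fractions")
  if (abs(sum(ratios) - 1) > 1e-9) stop("ratios must sum to 1")
  n <- length(ids)
  quota <- n * ratios
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  shuffled <- with_seed(seed, sample(ids))
  cuts <- cumsum(base)
  structure(list(train = shuffled[seq_len(base[1])],
                 val = if (base[2] > 0) shuffled[(cuts[1] + 1):cuts[2]] else character(0),
                 test = if (base[3] > 0) shuffled[(cuts[2] + 1):cuts[3]] else character(0),
                 ratios = ratios, seed = seed),
            class = "dataset_split")
}

#' Model and training configuration
#'
#' Collects every tunable of the architecture and the optimiser, with
#' validation. Long-range patches must have a strictly lower patch-to-stride
#' resolution (P/Str) than short-range patches; the shipped defaults are
#' P=16, Str=16 (resolution 1) for the long scale and P=4, Str=1
#' (resolution 4) for the short scale.
#'
#' @param d_model Shared latent dimension of the temporal experts.
#' @param patch_long_len,patch_long_stride Long-scale patch length and stride.
#' @param patch_short_len,patch_short_stride Short-scale patch length and stride.
#' @param mamba_hidden,mamba_state,mamba_conv_kernel Selective state-space
#'   expert sizes (hidden channels, state dimension, causal conv kernel).
#' @param lwt_heads,lwt_head_dim,lwt_ff_dim,lwt_window,lwt_layers Local-window
#'   attention expert sizes: heads, per-head dim, feed-forward dim, window
#'   width w (positions attend within |i-j| <= floor(w/2)), stacked layers.
#' @param router_dim Dimension of the global-context vector feeding the
#'   long-short router.
#' @param channel_mode "per_channel" applies the temporal experts to each
#'   univariate channel and averages the fused token matrices; "pooled"
#'   applies them to the channel-mean series (one pass per modality).
#' @param n_units Number of stacked fusion units.
#' @param gate_hidden Hidden width of the path/fusion gating networks.
#' @param lambda Weight of the expected-cost penalty in the loss (>= 0).
#' @param tau_start,tau_end Gumbel-Softmax temperature schedule endpoints
#'   (annealed geometrically from high to low; 0 < tau_end <= tau_start).
#' @param path_policy "thresholded" uses the confidence-threshold branching
#'   (0.75 / 0.9 / 0.4) at inference; "argmax" uses the plain argmax gate.
#' @param loss "cross_entropy" or "focal".
#' @param focal_gamma Focusing parameter for the focal loss.
#' @param lr,batch_size,max_epochs,patience,seed Optimiser settings: Adam
#'   learning rate, minibatch size, epoch cap, early-stopping patience on
#'   validation loss, and the seed fixing all randomness.
#' @param split_ratios Train/val/test ratios used by [train_model()].
#' @param cost_mode "nominal" uses the tiered GFLOP costs in [cost_model()];
#'   "analytic" uses the package's elementary-op counts.
#' @return A validated \code{dynfuse_config} list.
#' @export
run_config <- function(d_model = 256L,
                       patch_long_len = 16L, patch_long_stride = 16L,
                       patch_short_len = 4L, patch_short_stride = 1L,
                       mamba_hidden = 1024L, mamba_state = 16L,
                       mamba_conv_kernel = 4L,
                       lwt_heads = 8L, lwt_head_dim = 64L, lwt_ff_dim = 2048L,
                       lwt_window = 5L, lwt_layers = 2L,
                       router_dim = 16L,
                       channel_mode = c("per_channel", "pooled"),
                       n_units = 4L, gate_hidden = 256L,
                       lambda = 0.01, tau_start = 5.0, tau_end = 0.1,
                       path_policy = c("thresholded", "argmax"),
                       loss = c("cross_entropy", "focal"), focal_gamma = 2,
                       lr = 1e-4, batch_size = 16L, max_epochs = 120L,
                       patience = 15L, seed = 42L,
                       split_ratios = c(0.7, 0.1, 0.2),
                       cost_mode = c("nominal", "analytic")) {
  cfg <- list(d_model = as.integer(d_model),
              patch_long_len = as.integer(patch_long_len),
              patch_long_stride = as.integer(patch_long_stride),
              patch_short_len = as.integer(patch_short_len),
              patch_short_stride = as.integer(patch_short_stride),
              mamba_hidden = as.integer(mamba_hidden),
              mamba_state = as.integer(mamba_state),
              mamba_conv_kernel = as.integer(mamba_conv_kernel),
              lwt_heads = as.integer(lwt_heads),
              lwt_head_dim = as.integer(lwt_head_dim),
              lwt_ff_dim = as.integer(lwt_ff_dim),
              lwt_window = as.integer(lwt_window),
              lwt_layers = as.integer(lwt_layers),
              router_dim = as.integer(router_dim),
              channel_mode = match.arg(channel_mode),
              n_units = as.integer(n_units),
              gate_hidden = as.integer(gate_hidden),
              lambda = lambda, tau_start = tau_start, tau_end = tau_end,
              path_policy = match.arg(path_policy),
              loss = match.arg(loss), focal_gamma = focal_gamma,
              lr = lr, batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience), seed = as.integer(seed),
              split_ratios = split_ratios,
              cost_mode = match.arg(cost_mode))
  dims <- c("d_model", "patch_long_len", "patch_long_stride", "patch_short_len",
            "patch_short_stride", "mamba_hidden", "mamba_state",
            "mamba_conv_kernel", "lwt_heads", "lwt_head_dim", "lwt_ff_dim",
            "lwt_window", "lwt_layers", "router_dim", "n_units", "gate_hidden",
            "batch_size", "max_epochs")
  for (nm in dims) if (cfg[[nm]] < 1L) stop("config: ", nm, " must be >= 1")
  if (cfg$patience < 0L) stop("config: patience must be >= 0")
  if (cfg$lambda < 0) stop("config: lambda must be >= 0")
  if (!(cfg$tau_end > 0 && cfg$tau_end <= cfg$tau_start))
    stop("config: need 0 < tau_end <= tau_start")
  r_long <- cfg$patch_long_len / cfg$patch_long_stride
  r_short <- cfg$patch_short_len / cfg$patch_short_stride
  if (!(r_long < r_short))
    stop("config: long-range patch resolution (P/Str = ", r_long,
         ") must be lower than short-range resolution (", r_short, ")")
  if (abs(sum(cfg$split_ratios) - 1) > 1e-9)
    stop("config: split_ratios must sum to 1")
  class(cfg) <- "dynfuse_config"
  cfg
}
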