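# Per-modality multi-scale temporal expert pipeline (MTEM): each univariate
# channel is patched at a long and a short scale, encoded by the selective
# state-space expert and the local-window attention expert respectively, and
# the two encodings are combined by a learned two-way router conditioned on
# the channel's global context.

#' Global context vector of a series
#'
#' Time-mean pooling followed by a linear map: a permutation-invariant
#' summary of the overall level of the series that conditions the long-short
#' router.
#'
#' @param series Numeric vector (length L) or L x d matrix.
#' @param proj List with \code{W} (d_in x D) and \code{b} (1 x D) matrices,
#'   or the equivalent \code{ad_param} pair from a model.
#' @return 1 x D numeric matrix.
#' @export
global_context <- function(series, proj) {
  x <- as.matrix(series)
  if (nrow(x) < 1L) stop("empty series")
  mu <- matrix(colMeans(x), 1L)
  W <- if (inherits(proj$W, "ad_param")) proj$W$val else proj$W
  b <- if (inherits(proj$b, "ad_param")) proj$b$val else proj$b
  mu %*% W + matrix(as.numeric(b), 1L, ncol(W))
}

#' Two-way long-short routing probabilities
#'
#' Softmax over two logits computed from the global context:
#' (p_long, p_short) with p_long + p_short = 1.
#'
#' @param z_B 1 x D global context (from [global_context()]).
#' @param router List with \code{W} (D x 2) and \code{b} (1 x 2).
#' @return Named numeric vector \code{c(p_long, p_short)}.
#' @export
route_long_short <- function(z_B, router) {
  if (!all(is.finite(z_B))) stop("non-finite global context")
  W <- if (inherits(router$W, "ad_param")) router$W$val else router$W
  b <- if (inherits(router$b, "ad_param")) router$b$val else router$b
  z <- as.numeric(as.matrix(z_B) %*% W + matrix(as.numeric(b), 1L, 2L))
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  c(p_long = p[1], p_short = p[2])
}

#' Fuse long- and short-scale encodings
#'
#' Scales each expert's token matrix by its routing weight and concatenates
#' along the sequence (row) dimension, giving exactly N_L + N_S rows.
#'
#' @param z_L N_L x D long-scale encoding.
#' @param z_S N_S x D short-scale encoding.
#' @param p Routing weights \code{c(p_long, p_short)}.
#' @return (N_L + N_S) x D matrix.
#' @export
fuse_long_short <- function(z_L, z_S, p) {
  if (ncol(z_L) != ncol(z_S)) stop("z_L and z_S must share their feature dim")
  rbind(p[1] * z_L, p[2] * z_S)
}

#' Parameters for one modality's MTEM pipeline
#'
#' One router per modality, shared across its channels; per-scale linear
#' patch embeddings; one selective state-space block for the long scale and a
#' stack of local-window transformer layers for the short scale.
#'
#' @param cfg A [run_config()].
#' @param max_short_tokens Capacity of the learnable positional table (at
#'   least the short-scale patch count of the longest expected series).
#' @return Parameter list for [mtem_forward()]. Initialisation draws from the
#'   current RNG stream.
#' @export
mtem_params <- function(cfg, max_short_tokens = 256L) {
  d <- cfg$d_model
  list(
    embed_long = new_linear(cfg$patch_long_len, d),
    embed_short = new_linear(cfg$patch_short_len, d),
    pos = ad_param(matrix(stats::rnorm(max_short_tokens * d, 0, 0.05),
                          max_short_tokens, d)),
    mamba = mamba_params(d, cfg$mamba_hidden, cfg$mamba_state,
                         cfg$mamba_conv_kernel),
    lwt = lapply(seq_len(cfg$lwt_layers), function(i)
      lwt_params(d, cfg$lwt_heads, cfg$lwt_head_dim, cfg$lwt_ff_dim)),
    ctx = new_linear(1L, cfg$router_dim),
    router = new_linear(cfg$router_dim, 2L)
  )
}

mtem_channel_ad <- function(tape, ch, p, cfg, record = NULL, label = "mtem") {
  long <- make_patches(ch, patch_spec(cfg$patch_long_len,
                                      cfg$patch_long_stride, "long"))
  short <- make_patches(ch, patch_spec(cfg$patch_short_len,
                                       cfg$patch_short_stride, "short"))
  zl <- ad_linear(tape, ad_const(tape, long$patches), p$embed_long)
  zl <- mamba_block_ad(tape, zl, p$mamba)
  zs <- ad_linear(tape, ad_const(tape, short$patches), p$embed_short)
  zs <- add_positional(zs, p$pos, tape = tape)
  for (lp in p$lwt) zs <- lwt_block_ad(tape, zs, lp, cfg$lwt_window, record, label)
  zb <- ad_linear(tape, ad_const(tape, matrix(mean(ch), 1L, 1L)), p$ctx)
  pr <- ad_softmax_rows(tape, ad_linear(tape, zb, p$router))
  fused <- ad_concat_rows(tape, list(
    ad_scalar_mul(tape, zl, ad_pick(tape, pr, 1L, 1L)),
    ad_scalar_mul(tape, zs, ad_pick(tape, pr, 1L, 2L))))
  list(fused = fused, p = as.numeric(pr$val))
}

#' MTEM forward pass for one modality
#'
#' Splits the modality matrix into univariate channels (or their mean series
#' under \code{channel_mode = "pooled"}), runs each channel through the
#' long-scale (state-space) and short-scale (windowed-attention) experts,
#' routes the two encodings with the modality's long-short router, and
#' averages the fused per-channel token matrices into one token matrix of
#' N_L + N_S rows.
#'
#' @param x L x D_m modality feature matrix.
#' @param params An [mtem_params()] list.
#' @param cfg A [run_config()].
#' @param tape Optional autodiff tape (training); NULL runs forward-only.
#' @param record Optional attention-recording environment.
#' @param label Label prefix for recorded attention maps.
#' @return List with \code{tokens} ((N_L + N_S) x d_model matrix, or node
#'   when a tape is supplied) and \code{router} (per-channel matrix of
#'   p_long, p_short).
#' @export
mtem_forward <- function(x, params, cfg, tape = NULL, record = NULL,
                         label = "mtem") {
  x <- as.matrix(x)
  if (nrow(x) < max(cfg$patch_long_len, cfg$patch_short_len))
    stop("series length ", nrow(x), " shorter than the largest patch; need ",
         max(cfg$patch_long_len, cfg$patch_short_len), " steps")
  channels <- if (cfg$channel_mode == "per_channel") split_modalities(x)
              else list(rowMeans(x))
  own_tape <- is.null(tape)
  tp <- if (own_tape) ad_tape() else tape
  outs <- lapply(seq_along(channels), function(i)
    mtem_channel_ad(tp, channels[[i]], params, cfg, record,
                    sprintf("%s/ch%d", label, i)))
  fused <- lapply(outs, `[[`, "fused")
  tokens <- if (length(fused) == 1L) fused[[1]]
            else ad_scale(tp, Reduce(function(a, b) ad_add(tp, a, b), fused),
                          1 / length(fused))
  router <- do.call(rbind, lapply(outs, `[[`, "p"))
  colnames(router) <- c("p_long", "p_short")
  list(tokens = if (own_tape) tokens$val else tokens, router = router)
}
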