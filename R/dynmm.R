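# Dynamic multimodal fusion: a path gate selects one of four modality-level
# experts of increasing cost (audio-only up to deep audio-visual fusion);
# stacked fusion units then each select one of four fusion operations. At
# inference decisions are hard one-hots (only the chosen sub-network runs);
# during training they are Gumbel-Softmax samples with straight-through
# gradients, and the expected cost of the soft decisions is penalised.

#' Nominal cost model for experts and fusion operations
#'
#' Expert costs are the tiered per-sample GFLOP figures of the four
#' processing pathways (audio-only 0.6, audio + lightweight video 1.0,
#' audio + full video 1.6, deep audio-visual 2.3). Fusion-operation costs are
#' nominal tiers on the same relative ladder; only their ordering and rough
#' ratios matter to the resource-aware loss. The package's elementary-op
#' counter provides an analytic alternative (\code{cost_mode = "analytic"}).
#'
#' @return List with \code{expert_cost} (named E1..E4) and \code{op_cost}
#'   (named O1..O4), both strictly increasing.
#' @export
cost_model <- function() {
  list(expert_cost = c(E1 = 0.6, E2 = 1.0, E3 = 1.6, E4 = 2.3),
       op_cost = c(O1 = 0.05, O2 = 0.12, O3 = 0.25, O4 = 0.45))
}

ca_params <- function(d, heads, head_dim) {
  dk <- heads * head_dim
  list(Wq = new_linear(d, dk), Wk = new_linear(d, dk), Wv = new_linear(d, dk),
       Wo = new_linear(dk, d))
}

# multi-head cross attention: queries from xq, keys/values from xkv
cross_attn_ad <- function(tape, xq, xkv, p, heads, head_dim, record = NULL,
                          label = "cross") {
  q <- ad_linear(tape, xq, p$Wq)
  k <- ad_linear(tape, xkv, p$Wk)
  v <- ad_linear(tape, xkv, p$Wv)
  ctx <- ad_mha_dense(tape, q, k, v, heads, record = record, label = label)
  ad_linear(tape, ctx, p$Wo)
}

# full (unbanded) self-attention block reusing the LWT layer with a window
# covering the whole sequence
self_block_ad <- function(tape, x, p, record = NULL, label = "self") {
  lwt_block_ad(tape, x, p, w = 4L * nrow(x$val), record = record, label = label)
}

#' Parameters for the dynamic multimodal fusion stage
#'
#' Builds the light audio encoder, path gate, the four expert networks
#' (shared skeleton, tier-dependent depth), the global fusion gate and the
#' per-unit fusion-operation parameters.
#'
#' @param cfg A [run_config()].
#' @param compress_seed Seed of the fixed Gaussian projection used by the
#'   lightweight-video pathway.
#' @return Parameter list for [dynmm_forward()]. Initialisation draws from
#'   the current RNG stream.
#' @export
dynmm_params <- function(cfg, compress_seed = 1234L) {
  d <- cfg$d_model
  eh <- 2L; ehd <- max(2L, d %/% 2L); effd <- 2L * d   # expert attention sizes
  ch <- 4L; chd <- max(2L, d %/% 4L)                   # cross-attention sizes
  dr <- max(2L, d %/% 4L)                              # O2 reduced dim
  cell_params <- function() list(
    o1 = list(self_gate = new_linear(d, d), pool = new_linear(d, d)),
    o2 = list(Wq = new_linear(d, dr), Wk = new_linear(d, dr),
              Wv = new_linear(d, dr), Wo = new_linear(dr, d),
              gate = new_linear(d, d)),
    o3 = list(ca_v = ca_params(d, ch, chd), ca_a = ca_params(d, ch, chd)),
    o4 = list(ca1 = ca_params(d, ch, chd), ca2 = ca_params(d, ch, chd),
              ca3 = ca_params(d, ch, chd),
              dec = lwt_params(d, 2L, max(2L, d %/% 2L), 2L * d))
  )
  list(
    lae = list(conv_w = ad_param(matrix(stats::rnorm(3L * d, 0, 0.05), 3L, d)),
               conv_b = ad_param(matrix(0, 1L, d)),
               lin = new_linear(d, 512L)),
    gate1 = new_linear(512L, cfg$gate_hidden),
    gate2 = new_linear(cfg$gate_hidden, 4L),
    e1 = list(sa = lwt_params(d, eh, ehd, effd)),
    e2 = list(vproj = new_linear(min(d, max(8L, d %/% 4L)), d),
              sa = lwt_params(d, eh, ehd, effd)),
    e3 = list(sa_a = lwt_params(d, eh, ehd, effd),
              sa_v = lwt_params(d, eh, ehd, effd),
              ca_av = ca_params(d, ch, chd), ca_va = ca_params(d, ch, chd)),
    e4 = list(sa_a = lwt_params(d, eh, ehd, effd),
              sa_v = lwt_params(d, eh, ehd, effd),
              ca = lapply(1:3, function(i)
                list(av = ca_params(d, ch, chd), va = ca_params(d, ch, chd)))),
    fgate1 = new_linear(2L * d, cfg$gate_hidden),
    fgate2 = new_linear(cfg$gate_hidden, 4L * cfg$n_units),
    cells = lapply(seq_len(cfg$n_units), function(j) cell_params()),
    compress_seed = as.integer(compress_seed),
    dims = list(d = d, ch = ch, chd = chd, dr = dr, n_units = cfg$n_units)
  )
}

#' Light audio encoder
#'
#' A cheap fixed-size summary of the audio token sequence used by the path
#' gate: depthwise 1-d convolution (replicate padding, so a constant input
#' yields a length-independent output), SiLU, global average pooling over
#' time, and a linear map to a 512-dimensional descriptor.
#'
#' @param audio_tokens N x d matrix (or node with \code{tape}).
#' @param params A [dynmm_params()] list (its \code{lae} component is used).
#' @param tape Optional autodiff tape.
#' @return 1 x 512 matrix (or node).
#' @export
light_audio_encode <- function(audio_tokens, params, tape = NULL) {
  lae <- params$lae
  run <- function(tp, x) {
    cv <- ad_silu(tp, ad_causal_conv1d(tp, x, lae$conv_w, lae$conv_b,
                                       pad = "replicate"))
    ad_linear(tp, ad_rowmean(tp, cv), lae$lin)
  }
  if (is_ad_node(audio_tokens)) return(run(tape, audio_tokens))
  if (nrow(as.matrix(audio_tokens)) < 1L) stop("empty audio token sequence")
  tp <- ad_tape()
  run(tp, ad_const(tp, as.matrix(audio_tokens)))$val
}

path_gate_ad <- function(tape, fa, params, training) {
  h <- ad_relu(tape, ad_linear(tape, fa, params$gate1))
  h <- ad_dropout(tape, h, 0.2, training)
  logits <- ad_linear(tape, h, params$gate2)
  list(logits = logits, probs = ad_softmax_rows(tape, logits))
}

#' Path-gate scores
#'
#' Maps the 512-d light audio descriptor to four path probabilities:
#' Linear(512 -> gate hidden), ReLU, Dropout(0.2, training only),
#' Linear(-> 4), softmax.
#'
#' @param f_a 1 x 512 descriptor from [light_audio_encode()].
#' @param params A [dynmm_params()] list.
#' @param training Logical; enables dropout.
#' @return Numeric length-4 probability vector summing to 1.
#' @export
path_gate_scores <- function(f_a, params, training = FALSE) {
  if (!all(is.finite(as.matrix(f_a)))) stop("non-finite gate input")
  tp <- ad_tape()
  as.numeric(path_gate_ad(tp, ad_const(tp, as.matrix(f_a)), params,
                          training)$probs$val)
}

#' Threshold-based path selection
#'
#' The confidence-threshold branching used at inference: with confidence
#' (max probability) above 0.75, take the argmax path, except that a
#' non-audio-only argmax with confidence at or below 0.9 is bumped to the
#' next more complex path (min(p + 1, 4)); below the 0.75 confidence bar the
#' sample defaults to path 2 when the audio-only score exceeds 0.4 and to
#' path 4 otherwise. Ties in the argmax break to the lowest index.
#'
#' @param scores Length-4 probability vector (sums to 1).
#' @return Path index in 1..4.
#' @export
select_path <- function(scores) {
  stopifnot(length(scores) == 4L)
  conf <- max(scores)
  if (conf > 0.75) {
    p <- which.max(scores)
    if (p == 1L) return(1L)
    if (conf > 0.9) return(as.integer(p))
    return(as.integer(min(p + 1L, 4L)))
  }
  if (scores[1] > 0.4) return(2L)
  4L
}

#' Compressed-sensing style video reduction
#'
#' Projects the video feature dimension through a fixed seeded Gaussian
#' matrix scaled by 1/sqrt(m) (m = reduced dim), preserving squared norms in
#' expectation (Johnson-Lindenstrauss scaling). Token count is unchanged;
#' the measurement is used directly, with no reconstruction step.
#'
#' @param video N x D token matrix.
#' @param seed Integer seed fixing the projection.
#' @param out_dim Reduced dimension; default \code{min(D, max(8, D %/% 4))}.
#' @return N x out_dim matrix.
#' @export
compress_video <- function(video, seed, out_dim = NULL) {
  video <- as.matrix(video)
  D <- ncol(video)
  m <- if (is.null(out_dim)) min(D, max(8L, D %/% 4L)) else as.integer(out_dim)
  if (m > D) stop("reduced dim exceeds feature dim")
  P <- with_seed(seed, matrix(stats::rnorm(D * m), D, m)) / sqrt(m)
  video %*% P
}

expert_ad <- function(tape, k, x_a, x_v, params, record = NULL) {
  d <- params$dims$d; ch <- params$dims$ch; chd <- params$dims$chd
  if (k == 1L) {
    return(self_block_ad(tape, x_a, params$e1$sa, record, "E1/self"))
  }
  if (is.null(x_v)) stop("expert E", k, " requires video features")
  if (k == 2L) {
    D <- ncol(x_v$val)
    m <- min(D, max(8L, D %/% 4L))
    P <- with_seed(params$compress_seed, matrix(stats::rnorm(D * m), D, m)) / sqrt(m)
    vc <- ad_matmul(tape, x_v, ad_const(tape, P))
    vp <- ad_linear(tape, vc, params$e2$vproj)
    xx <- ad_concat_rows(tape, list(x_a, vp))
    return(self_block_ad(tape, xx, params$e2$sa, record, "E2/self"))
  }
  if (k == 3L) {
    a1 <- self_block_ad(tape, x_a, params$e3$sa_a, record, "E3/self-a")
    v1 <- self_block_ad(tape, x_v, params$e3$sa_v, record, "E3/self-v")
    a2 <- ad_add(tape, a1, cross_attn_ad(tape, a1, v1, params$e3$ca_av, ch, chd,
                                         record, "E3/a2v"))
    v2 <- ad_add(tape, v1, cross_attn_ad(tape, v1, a1, params$e3$ca_va, ch, chd,
                                         record, "E3/v2a"))
    return(ad_concat_rows(tape, list(a2, v2)))
  }
  if (k == 4L) {
    a <- self_block_ad(tape, x_a, params$e4$sa_a, record, "E4/self-a")
    v <- self_block_ad(tape, x_v, params$e4$sa_v, record, "E4/self-v")
    for (i in 1:3) {
      a2 <- ad_add(tape, a, cross_attn_ad(tape, a, v, params$e4$ca[[i]]$av,
                                          ch, chd, record,
                                          sprintf("E4/a2v-%d", i)))
      v2 <- ad_add(tape, v, cross_attn_ad(tape, v, a, params$e4$ca[[i]]$va,
                                          ch, chd, record,
                                          sprintf("E4/v2a-%d", i)))
      a <- a2; v <- v2
    }
    return(ad_concat_rows(tape, list(a, v)))
  }
  stop("expert index must be in 1..4, got ", k)
}

#' Run one modality-level expert
#'
#' Executes exactly the selected expert pathway: E1 audio-only self-attention
#' encoder (the video argument is never read); E2 audio plus compressed
#' video, concatenated token-wise and jointly encoded; E3 audio plus full
#' video with one bidirectional cross-attention layer; E4 the deep variant
#' with three stacked bidirectional cross-attention layers.
#'
#' @param k Expert index 1..4.
#' @param x_a Audio token matrix (or node with \code{tape}).
#' @param x_v Video token matrix; may be NULL only when k = 1.
#' @param params A [dynmm_params()] list.
#' @param tape Optional autodiff tape.
#' @param record Optional attention-recording environment.
#' @return Token matrix (or node); row count depends on the pathway.
#' @export
run_modality_expert <- function(k, x_a, x_v = NULL, params, tape = NULL,
                                record = NULL) {
  k <- as.integer(k)
  if (!k %in% 1:4) stop("expert index must be in 1..4, got ", k)
  if (k >= 2L && is.null(x_v)) stop("expert E", k, " requires video features")
  if (is_ad_node(x_a))
    return(expert_ad(tape, k, x_a, x_v, params, record))
  tp <- ad_tape()
  xa <- ad_const(tp, as.matrix(x_a))
  xv <- if (!is.null(x_v)) ad_const(tp, as.matrix(x_v)) else NULL
  expert_ad(tp, k, xa, xv, params, record)$val
}

fusion_op_ad <- function(tape, op, st, cp, dims, record = NULL, label = "cell") {
  h <- st$h
  if (op == 1L) {
    # audio-internal multi-level aggregation: no cross-modal input
    pooled <- ad_linear(tape, ad_rowmean(tape, st$a), cp$o1$pool)
    gate <- ad_sigmoid(tape, ad_linear(tape, h, cp$o1$self_gate))
    upd <- ad_mul(tape, ad_broadcast_rows(tape, pooled, nrow(h$val)), gate)
    return(ad_add(tape, h, upd))
  }
  if (op == 2L) {
    # gated single-head cross-attention at reduced dimension
    q <- ad_linear(tape, h, cp$o2$Wq)
    k <- ad_linear(tape, st$v, cp$o2$Wk)
    v <- ad_linear(tape, st$v, cp$o2$Wv)
    ctx <- ad_linear(tape, ad_attention_dense(tape, q, k, v, record = record,
                                              label = paste0(label, "/O2")),
                     cp$o2$Wo)
    gate <- ad_sigmoid(tape, ad_linear(tape, h, cp$o2$gate))
    return(ad_add(tape, h, ad_mul(tape, ctx, gate)))
  }
  if (op == 3L) {
    # bidirectional multi-head cross-attention with residuals
    hv <- cross_attn_ad(tape, h, st$v, cp$o3$ca_v, dims$ch, dims$chd, record,
                        paste0(label, "/O3-v"))
    ha <- cross_attn_ad(tape, h, st$a, cp$o3$ca_a, dims$ch, dims$chd, record,
                        paste0(label, "/O3-a"))
    return(ad_add(tape, ad_add(tape, h, hv), ha))
  }
  if (op == 4L) {
    # three-level co-attention stack followed by a self-attention decoder
    l1 <- ad_add(tape, h, cross_attn_ad(tape, h, st$v, cp$o4$ca1, dims$ch,
                                        dims$chd, record, paste0(label, "/O4-1")))
    l2 <- ad_add(tape, l1, cross_attn_ad(tape, l1, st$a, cp$o4$ca2, dims$ch,
                                         dims$chd, record, paste0(label, "/O4-2")))
    l3 <- ad_add(tape, l2, cross_attn_ad(tape, l2, st$v, cp$o4$ca3, dims$ch,
                                         dims$chd, record, paste0(label, "/O4-3")))
    return(self_block_ad(tape, l3, cp$o4$dec, record, paste0(label, "/O4-dec")))
  }
  stop("fusion operation index must be in 1..4, got ", op)
}

#' Run one fusion unit
#'
#' Executes only the selected operation of unit j on the running fused state:
#' O1 audio-internal aggregation (no cross-modal input), O2 gated single-head
#' cross-attention at reduced dimension, O3 bidirectional multi-head
#' cross-attention, O4 a three-level co-attention stack with a
#' self-attention decoder block.
#'
#' @param j Fusion-unit index.
#' @param state List with \code{a} (audio tokens), \code{v} (video tokens)
#'   and \code{h} (current fused state), matrices or nodes.
#' @param decision One-hot length-4 vector (or a bare op index 1..4).
#' @param params A [dynmm_params()] list.
#' @param tape Optional autodiff tape.
#' @param record Optional attention-recording environment.
#' @return Updated fused state h_j (matrix or node).
#' @export
fusion_cell_forward <- function(j, state, decision, params, tape = NULL,
                                record = NULL) {
  op <- if (length(decision) == 1L) as.integer(decision)
        else {
          if (sum(decision == 1) != 1L || sum(decision) != 1)
            stop("hard fusion decision must be one-hot")
          which.max(decision)
        }
  if (!op %in% 1:4) stop("fusion operation index must be in 1..4, got ", op)
  cp <- params$cells[[j]]
  if (is_ad_node(state$h))
    return(fusion_op_ad(tape, op, state, cp, params$dims, record,
                        sprintf("cell%d", j)))
  tp <- ad_tape()
  st <- list(a = ad_const(tp, as.matrix(state$a)),
             v = if (!is.null(state$v)) ad_const(tp, as.matrix(state$v)) else NULL,
             h = ad_const(tp, as.matrix(state$h)))
  fusion_op_ad(tp, op, st, cp, params$dims, record, sprintf("cell%d", j))$val
}

#' Expected computational cost of soft decisions
#'
#' The probability-weighted cost sum_i p_i C(E_i) + sum_j sum_k pi_jk C(O_k),
#' in the cost model's units (GFLOPs for the nominal model).
#'
#' @param path_probs Length-4 expert selection probabilities (sum to 1).
#' @param fusion_probs NULL, a 4-vector, a list of 4-vectors, or an
#'   n_units x 4 matrix of per-unit operation probabilities.
#' @param cost Cost model from [cost_model()].
#' @return A single number.
#' @export
expected_cost <- function(path_probs, fusion_probs = NULL, cost = cost_model()) {
  if (abs(sum(path_probs) - 1) > 1e-6)
    stop("path probabilities must sum to 1")
  total <- sum(path_probs * cost$expert_cost)
  if (!is.null(fusion_probs)) {
    if (is.numeric(fusion_probs) && is.null(dim(fusion_probs)))
      fusion_probs <- matrix(fusion_probs, nrow = 1L)
    if (is.list(fusion_probs))
      fusion_probs <- do.call(rbind, fusion_probs)
    if (any(abs(rowSums(fusion_probs) - 1) > 1e-6))
      stop("fusion probabilities must sum to 1 per unit")
    total <- total + sum(fusion_probs %*% cost$op_cost)
  }
  total
}

path_decision <- function(scores, selected) {
  hard <- numeric(4L); hard[selected] <- 1
  list(scores = as.numeric(scores), confidence = max(scores),
       selected = as.integer(selected), hard = hard)
}

#' Dynamic multimodal fusion forward pass
#'
#' Full stage: light audio encoding, path gating, execution of the single
#' selected expert, then the stack of fusion units each executing its single
#' selected operation, returning the final fused state and all decisions.
#' In hard mode (inference) decisions are deterministic one-hots — via the
#' confidence-threshold policy or plain argmax per the config. In soft mode
#' (training) decisions are Gumbel-Softmax samples at temperature \code{tau};
#' the argmax branch executes and straight-through scaling routes gradients
#' into the soft probabilities. \code{force_path} / \code{force_ops} bypass
#' the gates entirely (then nothing outside the forced sub-networks runs).
#'
#' @param x_a Audio token matrix from the audio MTEM (or node).
#' @param x_v Video token matrix (may be NULL when forcing path 1).
#' @param params A [dynmm_params()] list.
#' @param cfg A [run_config()].
#' @param mode "hard" or "soft".
#' @param tau Gumbel-Softmax temperature (soft mode).
#' @param force_path Optional fixed expert index 1..4.
#' @param force_ops Optional fixed op index (recycled) or length-n_units
#'   vector.
#' @param training Logical; enables dropout in the gates.
#' @param tape Optional autodiff tape.
#' @param record Optional attention-recording environment.
#' @return List with \code{h} (final fused state; matrix or node),
#'   \code{path} (scores, confidence, selected index, one-hot),
#'   \code{fusion} (per-unit probs and one-hots), and in soft/tape mode the
#'   probability nodes needed by the resource-aware loss.
#' @export
dynmm_forward <- function(x_a, x_v = NULL, params, cfg,
                          mode = c("hard", "soft"), tau = 1,
                          force_path = NULL, force_ops = NULL,
                          training = FALSE, tape = NULL, record = NULL) {
  mode <- match.arg(mode)
  own_tape <- is.null(tape)
  tp <- if (own_tape) ad_tape() else tape
  xa <- if (is_ad_node(x_a)) x_a else ad_const(tp, as.matrix(x_a))
  xv <- if (is.null(x_v)) NULL
        else if (is_ad_node(x_v)) x_v else ad_const(tp, as.matrix(x_v))
  n_units <- cfg$n_units
  path_probs_node <- NULL
  fusion_probs_node <- NULL

  if (!is.null(force_path)) {
    sel <- as.integer(force_path)
    pd <- path_decision(rep(0.25, 4L), sel)
    soft_path <- NULL
  } else {
    fa <- light_audio_encode(xa, params, tape = tp)
    g <- path_gate_ad(tp, fa, params, training)
    path_probs_node <- g$probs
    probs <- as.numeric(g$probs$val)
    if (mode == "hard") {
      sel <- if (cfg$path_policy == "thresholded") select_path(probs)
             else which.max(probs)
      pd <- path_decision(probs, sel)
      soft_path <- NULL
    } else {
      gum <- -log(-log(stats::runif(4L)))
      soft <- ad_softmax_rows(tp, ad_scale(tp,
        ad_add(tp, g$logits, ad_const(tp, matrix(gum, 1L))), 1 / tau))
      sel <- which.max(soft$val)
      pd <- path_decision(probs, sel)
      soft_path <- soft
    }
  }

  h <- expert_ad(tp, sel, xa, xv, params, record)
  if (!is.null(soft_path))
    h <- ad_ste_mul(tp, h, ad_pick(tp, soft_path, 1L, sel))

  if (!is.null(force_ops)) {
    ops <- rep_len(as.integer(force_ops), n_units)
    fprobs <- matrix(0.25, n_units, 4L)
    fhard <- t(vapply(ops, function(o) { v <- numeric(4L); v[o] <- 1; v },
                      numeric(4L)))
    for (j in seq_len(n_units)) {
      h <- fusion_op_ad(tp, ops[j], list(a = xa, v = xv, h = h),
                        params$cells[[j]], params$dims, record,
                        sprintf("cell%d", j))
    }
  } else {
    gin <- ad_concat_cols(tp, list(ad_rowmean(tp, xa),
                                   if (!is.null(xv)) ad_rowmean(tp, xv)
                                   else ad_const(tp, matrix(0, 1L, params$dims$d))))
    fh <- ad_relu(tp, ad_linear(tp, gin, params$fgate1))
    fh <- ad_dropout(tp, fh, 0.2, training)
    flogits <- ad_linear(tp, fh, params$fgate2)
    fprobs <- matrix(0, n_units, 4L)
    fhard <- matrix(0, n_units, 4L)
    ops <- integer(n_units)
    funit_nodes <- vector("list", n_units)
    for (j in seq_len(n_units)) {
      idx <- ((j - 1L) * 4L + 1L):(j * 4L)
      lj <- ad_cols(tp, flogits, idx)
      pj <- ad_softmax_rows(tp, lj)
      funit_nodes[[j]] <- pj
      fprobs[j, ] <- as.numeric(pj$val)
      if (mode == "hard") {
        ops[j] <- which.max(fprobs[j, ])
        softj <- NULL
      } else {
        gum <- -log(-log(stats::runif(4L)))
        softj <- ad_softmax_rows(tp, ad_scale(tp,
          ad_add(tp, lj, ad_const(tp, matrix(gum, 1L))), 1 / tau))
        ops[j] <- which.max(softj$val)
      }
      fhard[j, ops[j]] <- 1
      h <- fusion_op_ad(tp, ops[j], list(a = xa, v = xv, h = h),
                        params$cells[[j]], params$dims, record,
                        sprintf("cell%d", j))
      if (!is.null(softj))
        h <- ad_ste_mul(tp, h, ad_pick(tp, softj, 1L, ops[j]))
    }
    fusion_probs_node <- funit_nodes
  }

  list(h = if (own_tape) h$val else h,
       path = pd,
       fusion = list(probs = fprobs, hard = fhard,
                     selected = apply(fhard, 1L, which.max)),
       path_probs_node = path_probs_node,
       fusion_probs_node = fusion_probs_node)
}
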