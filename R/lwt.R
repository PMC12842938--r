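# Local Window Transformer (LWT) short-range expert: banded multi-head
# self-attention plus a position-wise feed-forward network, pre-norm residual
# ordering.

#' Banded attention mask
#'
#' Additive mask in the -1e9 convention: entry (i, j) is 0 when position j
#' lies within the symmetric window of position i (|i - j| <= floor(w/2)) and
#' -1e9 otherwise. Adding the mask to attention scores before the softmax
#' drives excluded weights to exactly zero (the exponential underflows).
#'
#' @param N Sequence length.
#' @param w Window width (>= 1); half-width is floor(w/2).
#' @return N x N numeric matrix of 0 / -1e9.
#' @export
band_mask <- function(N, w) {
  hw <- w %/% 2
  d <- abs(outer(seq_len(N), seq_len(N), "-"))
  m <- matrix(0, N, N)
  m[d > hw] <- -1e9
  m
}

#' Parameters for one local-window transformer layer
#'
#' @param d_model Model dimension.
#' @param heads Number of attention heads.
#' @param head_dim Dimension per head.
#' @param ff_dim Feed-forward hidden dimension.
#' @return Parameter list for [lwt_block()] / [windowed_mhsa()].
#'   Initialisation draws from the current RNG stream.
#' @export
lwt_params <- function(d_model, heads = 8L, head_dim = 64L, ff_dim = 2048L) {
  dk <- heads * head_dim
  p <- list(
    ln1 = new_layernorm(d_model),
    Wq = new_linear(d_model, dk), Wk = new_linear(d_model, dk),
    Wv = new_linear(d_model, dk), Wo = new_linear(dk, d_model),
    ln2 = new_layernorm(d_model),
    ff1 = new_linear(d_model, ff_dim), ff2 = new_linear(ff_dim, d_model)
  )
  attr(p, "dims") <- list(d_model = d_model, heads = heads,
                          head_dim = head_dim, ff_dim = ff_dim)
  p
}

windowed_mhsa_ad <- function(tape, x, p, w, record = NULL, label = "lwt") {
  dims <- attr(p, "dims")
  hw <- w %/% 2
  q <- ad_linear(tape, x, p$Wq)
  k <- ad_linear(tape, x, p$Wk)
  v <- ad_linear(tape, x, p$Wv)
  ctx <- ad_mha_banded(tape, q, k, v, dims$heads, hw, record = record,
                       label = label)
  ad_linear(tape, ctx, p$Wo)
}

#' Windowed multi-head self-attention
#'
#' Per head: scaled dot-product attention restricted to the symmetric local
#' window (|i - j| <= floor(w/2)); softmax rows therefore sum to 1 over the
#' allowed positions and weights outside the band are exactly zero. Heads are
#' concatenated and linearly projected. With w >= 2N the band covers the
#' whole sequence and the result equals dense full attention.
#'
#' @param x N x d_model matrix (or node with \code{tape}).
#' @param params An [lwt_params()] list.
#' @param w Window width.
#' @param tape Optional autodiff tape.
#' @param record Optional environment with a \code{maps} list; row-stochastic
#'   attention matrices are appended per head.
#' @return N x d_model matrix (or node).
#' @export
windowed_mhsa <- function(x, params, w, tape = NULL, record = NULL) {
  if (is_ad_node(x)) return(windowed_mhsa_ad(tape, x, params, w, record))
  if (!all(is.finite(x))) stop("non-finite input to windowed_mhsa")
  tp <- ad_tape()
  windowed_mhsa_ad(tp, ad_const(tp, as.matrix(x)), params, w, record)$val
}

lwt_block_ad <- function(tape, x, p, w, record = NULL, label = "lwt") {
  a <- windowed_mhsa_ad(tape, ad_ln(tape, x, p$ln1), p, w, record, label)
  x1 <- ad_add(tape, x, a)
  f <- ad_linear(tape,
                 ad_gelu(tape, ad_linear(tape, ad_ln(tape, x1, p$ln2), p$ff1)),
                 p$ff2)
  ad_add(tape, x1, f)
}

#' Local-window transformer layer
#'
#' Pre-norm ordering: LayerNorm then windowed MHSA with a residual
#' connection, LayerNorm then a GELU feed-forward network with a second
#' residual. Stacking l layers grows the receptive field to about l*w.
#'
#' @inheritParams windowed_mhsa
#' @return N x d_model matrix (or node).
#' @export
lwt_block <- function(x, params, w, tape = NULL, record = NULL) {
  if (is_ad_node(x)) return(lwt_block_ad(tape, x, params, w, record))
  if (!all(is.finite(x))) stop("non-finite input to lwt_block")
  tp <- ad_tape()
  lwt_block_ad(tp, ad_const(tp, as.matrix(x)), params, w, record)$val
}

#' Add learnable positional encodings
#'
#' Adds the first N rows of the position table to the input. Errors when the
#' sequence outgrows the table.
#'
#' @param x N x d_model matrix (or node with \code{tape}).
#' @param table Position table: a matrix with at least N rows, or an
#'   \code{ad_param} holding one.
#' @param tape Optional autodiff tape.
#' @return x + table[1:N, ].
#' @export
add_positional <- function(x, table, tape = NULL) {
  tab_rows <- if (inherits(table, "ad_param")) nrow(table$val) else nrow(table)
  n <- if (is_ad_node(x)) nrow(x$val) else nrow(x)
  if (n > tab_rows)
    stop("sequence length ", n, " exceeds positional table capacity ", tab_rows)
  if (is_ad_node(x)) {
    tnode <- if (inherits(table, "ad_param")) table else ad_const(tape, table)
    return(ad_add(tape, x, ad_rows(tape, tnode, seq_len(n))))
  }
  tabv <- if (inherits(table, "ad_param")) table$val else table
  x + tabv[seq_len(n), , drop = FALSE]
}
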