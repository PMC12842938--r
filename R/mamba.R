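# Selective state-space (Mamba-style) long-range expert.
#
# The block-internal recurrence is h_t = Abar_t * h_{t-1} + Bbar_t x_t with
# readout y_t = <C_t, h_t> per hidden channel, where Abar, Bbar, C are
# functions of the input at each step (the "selective" mechanism). The
# sequential scan_oracle() is the normative definition; selective_scan() must
# match it on every input.

#' Inputs for a selective scan
#'
#' Bundles the per-step discretised transition, input term and readout used by
#' [scan_oracle()] and [selective_scan()]. The initial state is the zero
#' state.
#'
#' @param Abar N x H x S array: elementwise state transition per step.
#' @param Bu N x H x S array: per-step input term (Bbar_t x_t).
#' @param C N x S matrix: per-step readout vector.
#' @return A \code{scan_inputs} list.
#' @export
scan_inputs <- function(Abar, Bu, C) {
  if (length(dim(Abar)) != 3L || !identical(dim(Abar), dim(Bu)))
    stop("Abar and Bu must be N x H x S arrays of identical shape")
  C <- as.matrix(C)
  if (nrow(C) != dim(Abar)[1] || ncol(C) != dim(Abar)[3])
    stop("C must be N x S, matching Abar's first and last dimensions")
  structure(list(Abar = Abar, Bu = Bu, C = C), class = "scan_inputs")
}

#' Sequential scan oracle
#'
#' Literal step-by-step evaluation of the selective recurrence:
#' h_t = Abar_t * h_{t-1} + Bu_t (elementwise over hidden x state), then
#' y_t[h] = sum_s h_t[h, s] C_t[s]. This is the normative definition that any
#' faster scan implementation must reproduce.
#'
#' @param inputs A [scan_inputs()] object.
#' @return N x H matrix of outputs.
#' @export
scan_oracle <- function(inputs) {
  stopifnot(inherits(inputs, "scan_inputs"))
  d <- dim(inputs$Abar); N <- d[1]; H <- d[2]; S <- d[3]
  y <- matrix(0, N, H)
  h <- matrix(0, H, S)
  for (t in seq_len(N)) {
    for (hh in seq_len(H)) {
      for (s in seq_len(S)) {
        h[hh, s] <- inputs$Abar[t, hh, s] * h[hh, s] + inputs$Bu[t, hh, s]
      }
      acc <- 0
      for (s in seq_len(S)) acc <- acc + h[hh, s] * inputs$C[t, s]
      y[t, hh] <- acc
    }
  }
  y
}

#' Selective scan
#'
#' Evaluates the same recurrence as [scan_oracle()] with vectorised per-step
#' updates; cost is linear in the sequence length (tracked by the package's
#' elementary-operation counter). Agrees with the oracle to floating-point
#' round-off.
#'
#' @param inputs A [scan_inputs()] object.
#' @return N x H matrix of outputs.
#' @export
selective_scan <- function(inputs) {
  stopifnot(inherits(inputs, "scan_inputs"))
  d <- dim(inputs$Abar); N <- d[1]; H <- d[2]; S <- d[3]
  y <- matrix(0, N, H)
  h <- matrix(0, H, S)
  for (t in seq_len(N)) {
    h <- matrix(inputs$Abar[t, , ], H, S) * h + matrix(inputs$Bu[t, , ], H, S)
    y[t, ] <- as.numeric(h %*% inputs$C[t, ])
  }
  count_flops(N * H * S * 4)
  y
}

#' Discretise continuous state-space parameters
#'
#' Zero-order-hold transition with Euler input rule, per step: Abar = exp(dt *
#' A) elementwise over the diagonal state matrix (A is H x S, one diagonal
#' per hidden channel), Bbar = dt * B. dt must be strictly positive (the
#' block guarantees this via softplus).
#'
#' @param A H x S state matrix (negative entries give contracting dynamics).
#' @param delta_t Length-H positive timescale vector for one step.
#' @param B_t Length-S input vector for one step.
#' @return List with \code{Abar} (H x S) and \code{Bbar} (H x S).
#' @export
discretize <- function(A, delta_t, B_t) {
  A <- as.matrix(A)
  if (any(delta_t <= 0)) stop("delta must be strictly positive")
  if (length(delta_t) != nrow(A)) stop("delta length must equal nrow(A)")
  list(Abar = exp(delta_t * A), Bbar = delta_t %o% as.numeric(B_t))
}

#' Parameters for a selective state-space block
#'
#' A is diagonal per hidden channel, parameterised A = -exp(a_log) with
#' a_log initialised to log(1..state_dim) so dynamics start stable and
#' contracting; a_log is trainable unless frozen.
#'
#' @param d_model Input/output dimension of the block.
#' @param hidden_dim Inner (expanded) channel count.
#' @param state_dim State dimension per hidden channel.
#' @param conv_kernel Causal depthwise convolution kernel length.
#' @param freeze_A If TRUE, a_log receives no gradient updates.
#' @return A parameter list usable by [mamba_block()]. Initialisation draws
#'   from the current RNG stream.
#' @export
mamba_params <- function(d_model, hidden_dim = 1024L, state_dim = 16L,
                         conv_kernel = 4L, freeze_A = FALSE) {
  p <- list(
    ln = new_layernorm(d_model),
    in_proj = new_linear(d_model, hidden_dim),
    conv_w = ad_param(matrix(stats::rnorm(conv_kernel * hidden_dim, 0, 0.05),
                             conv_kernel, hidden_dim)),
    conv_b = ad_param(matrix(0, 1L, hidden_dim)),
    dt_proj = new_linear(hidden_dim, hidden_dim),
    B_proj = new_linear(hidden_dim, state_dim),
    C_proj = new_linear(hidden_dim, state_dim),
    a_log = ad_param(matrix(log(seq_len(state_dim)), hidden_dim, state_dim,
                            byrow = TRUE)),
    gate_proj = new_linear(d_model, hidden_dim),
    out_proj = new_linear(hidden_dim, d_model)
  )
  attr(p, "freeze_A") <- freeze_A
  attr(p, "dims") <- list(d_model = d_model, hidden_dim = hidden_dim,
                          state_dim = state_dim, conv_kernel = conv_kernel)
  p
}

# graph-building core; x is a node
mamba_block_ad <- function(tape, x, p) {
  xn <- ad_ln(tape, x, p$ln)
  u0 <- ad_linear(tape, xn, p$in_proj)
  u1 <- ad_causal_conv1d(tape, u0, p$conv_w, p$conv_b)
  u <- ad_silu(tape, u1)
  delta <- ad_softplus(tape, ad_linear(tape, u, p$dt_proj))
  B <- ad_linear(tape, u, p$B_proj)
  C <- ad_linear(tape, u, p$C_proj)
  A <- if (isTRUE(attr(p, "freeze_A"))) ad_const(tape, -exp(p$a_log$val))
       else ad_scale(tape, ad_exp(tape, p$a_log), -1)
  y <- ad_selective_scan_op(tape, delta, B, C, u, A)
  gate <- ad_silu(tape, ad_linear(tape, x, p$gate_proj))
  yg <- ad_mul(tape, y, gate)
  out <- ad_linear(tape, yg, p$out_proj)
  ad_add(tape, out, x)
}

#' Selective state-space block
#'
#' Full block in the pseudocode order: LayerNorm, linear expansion to
#' hidden_dim, causal depthwise 1-d convolution, SiLU, input-dependent
#' parameters (dt via softplus-linear, B and C via linears), selective scan,
#' SiLU gate on a separate projection of the input, linear projection back to
#' d_model, residual connection. Shape-preserving and deterministic.
#'
#' @param x N x d_model numeric matrix (or an autodiff node when \code{tape}
#'   is supplied).
#' @param params A [mamba_params()] list.
#' @param tape Optional autodiff tape; when NULL the block runs forward-only
#'   and returns a plain matrix.
#' @return N x d_model matrix (or node).
#' @export
mamba_block <- function(x, params, tape = NULL) {
  if (is_ad_node(x)) return(mamba_block_ad(tape, x, params))
  if (!all(is.finite(x))) stop("non-finite input to mamba_block")
  tp <- ad_tape()
  mamba_block_ad(tp, ad_const(tp, as.matrix(x)), params)$val
}
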