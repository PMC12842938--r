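# Reverse-mode automatic differentiation on dense numeric arrays.
#
# A tape records nodes in creation order; ad_backward() replays closures in
# reverse. Nodes and parameters are environments so gradients accumulate in
# place. Values are plain matrices (scalars as 1x1), except the selective-scan
# internals which use 3-d arrays. Heavy primitives (attention, selective scan,
# causal conv, layer norm) are fused ops with hand-derived backward passes so
# graphs stay small enough for pure-R training loops.

the <- new.env(parent = emptyenv())
the$flops <- 0

#' Reset the elementary-operation counter
#'
#' The package keeps a global counter of multiply-accumulate operations
#' performed by its numerical primitives (matrix products, attention,
#' selective scans, convolutions). The counter underpins the analytic
#' cost accounting and the linear-complexity checks.
#' @return Invisibly, the counter value before the reset (a number).
#' @export
flop_counter_reset <- function() {
  old <- the$flops
  the$flops <- 0
  invisible(old)
}

#' Read the elementary-operation counter
#' @return Number of multiply-accumulate operations counted since the last
#'   reset.
#' @export
flop_counter_read <- function() the$flops

count_flops <- function(n) the$flops <- the$flops + n

# ---- tape and nodes ---------------------------------------------------------

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ad_node <- function(tape, val, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$backward <- backward
  if (!is.null(tape)) {
    n <- tape$n + 1L
    if (n > length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$nodes[[n]] <- nd
    tape$n <- n
  }
  nd
}

is_ad_node <- function(x) is.environment(x) && !is.null(x$val)

# Wrap a plain matrix/vector as a constant node (no backward).
ad_const <- function(tape, x) {
  if (is_ad_node(x)) return(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  ad_node(tape, x)
}

ad_acc <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
}

# Persistent trainable parameter (survives across tapes).
ad_param <- function(value) {
  p <- new.env(parent = emptyenv())
  if (is.null(dim(value))) value <- matrix(value, nrow = 1L)
  p$val <- value
  p$grad <- NULL
  class(p) <- "ad_param"
  p
}

# Use a parameter inside a graph; gradient flows into param$grad.
ad_leaf <- function(tape, param) {
  nd <- ad_node(tape, param$val, backward = function(nd) {
    param$grad <- if (is.null(param$grad)) nd$grad else param$grad + nd$grad
  })
  nd
}

# Run backward from a scalar output node.
ad_backward <- function(tape, out) {
  stopifnot(length(out$val) == 1L)
  out$grad <- matrix(1, 1L, 1L)
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
  invisible(NULL)
}

# ---- elementwise and linear ops --------------------------------------------

ad_add <- function(tape, a, b) {
  ad_node(tape, a$val + b$val, backward = function(nd) {
    ad_acc(a, nd$grad)
    ad_acc(b, nd$grad)
  })
}

ad_sub <- function(tape, a, b) {
  ad_node(tape, a$val - b$val, backward = function(nd) {
    ad_acc(a, nd$grad)
    ad_acc(b, -nd$grad)
  })
}

ad_mul <- function(tape, a, b) {
  ad_node(tape, a$val * b$val, backward = function(nd) {
    ad_acc(a, nd$grad * b$val)
    ad_acc(b, nd$grad * a$val)
  })
}

ad_scale <- function(tape, a, s) {
  ad_node(tape, a$val * s, backward = function(nd) ad_acc(a, nd$grad * s))
}

# multiply matrix node by scalar node (1x1)
ad_scalar_mul <- function(tape, x, s) {
  sv <- as.numeric(s$val)
  ad_node(tape, x$val * sv, backward = function(nd) {
    ad_acc(x, nd$grad * sv)
    ad_acc(s, matrix(sum(nd$grad * x$val), 1L, 1L))
  })
}

ad_matmul <- function(tape, a, b) {
  count_flops(2 * nrow(a$val) * ncol(a$val) * ncol(b$val))
  ad_node(tape, a$val %*% b$val, backward = function(nd) {
    ad_acc(a, nd$grad %*% t(b$val))
    ad_acc(b, t(a$val) %*% nd$grad)
  })
}

# x: N x d, b: 1 x d broadcast over rows
ad_add_bias <- function(tape, x, b) {
  bv <- as.numeric(b$val)
  ad_node(tape, x$val + rep(bv, each = nrow(x$val)), backward = function(nd) {
    ad_acc(x, nd$grad)
    ad_acc(b, matrix(colSums(nd$grad), 1L))
  })
}

ad_rows <- function(tape, x, idx) {
  nr <- nrow(x$val)
  ad_node(tape, x$val[idx, , drop = FALSE], backward = function(nd) {
    g <- matrix(0, nr, ncol(x$val))
    g[idx, ] <- g[idx, ] + nd$grad
    ad_acc(x, g)
  })
}

ad_cols <- function(tape, x, idx) {
  nc <- ncol(x$val)
  ad_node(tape, x$val[, idx, drop = FALSE], backward = function(nd) {
    g <- matrix(0, nrow(x$val), nc)
    g[, idx] <- g[, idx] + nd$grad
    ad_acc(x, g)
  })
}

ad_concat_rows <- function(tape, xs) {
  ns <- vapply(xs, function(x) nrow(x$val), integer(1))
  ad_node(tape, do.call(rbind, lapply(xs, function(x) x$val)), backward = function(nd) {
    at <- 0L
    for (i in seq_along(xs)) {
      ad_acc(xs[[i]], nd$grad[(at + 1L):(at + ns[i]), , drop = FALSE])
      at <- at + ns[i]
    }
  })
}

ad_concat_cols <- function(tape, xs) {
  ns <- vapply(xs, function(x) ncol(x$val), integer(1))
  ad_node(tape, do.call(cbind, lapply(xs, function(x) x$val)), backward = function(nd) {
    at <- 0L
    for (i in seq_along(xs)) {
      ad_acc(xs[[i]], nd$grad[, (at + 1L):(at + ns[i]), drop = FALSE])
      at <- at + ns[i]
    }
  })
}

# mean over rows -> 1 x d
ad_rowmean <- function(tape, x) {
  n <- nrow(x$val)
  ad_node(tape, matrix(colMeans(x$val), 1L), backward = function(nd) {
    ad_acc(x, matrix(rep(nd$grad / n, each = n), n))
  })
}

ad_mean_all <- function(tape, x) {
  n <- length(x$val)
  ad_node(tape, matrix(mean(x$val), 1L, 1L), backward = function(nd) {
    ad_acc(x, array(as.numeric(nd$grad) / n, dim = dim(x$val)))
  })
}

ad_pick <- function(tape, x, i, j) {
  ad_node(tape, matrix(x$val[i, j], 1L, 1L), backward = function(nd) {
    g <- matrix(0, nrow(x$val), ncol(x$val))
    g[i, j] <- as.numeric(nd$grad)
    ad_acc(x, g)
  })
}

ad_broadcast_rows <- function(tape, rowvec, n) {
  ad_node(tape, matrix(rep(as.numeric(rowvec$val), each = n), n),
          backward = function(nd) ad_acc(rowvec, matrix(colSums(nd$grad), 1L)))
}

# ---- activations ------------------------------------------------------------

ad_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$val))
  ad_node(tape, s, backward = function(nd) ad_acc(x, nd$grad * s * (1 - s)))
}

ad_silu <- function(tape, x) {
  s <- 1 / (1 + exp(-x$val))
  ad_node(tape, x$val * s, backward = function(nd) {
    ad_acc(x, nd$grad * (s + x$val * s * (1 - s)))
  })
}

ad_relu <- function(tape, x) {
  m <- x$val > 0
  ad_node(tape, x$val * m, backward = function(nd) ad_acc(x, nd$grad * m))
}

ad_gelu <- function(tape, x) {
  ph <- stats::pnorm(x$val)
  ad_node(tape, x$val * ph, backward = function(nd) {
    ad_acc(x, nd$grad * (ph + x$val * stats::dnorm(x$val)))
  })
}

ad_tanh <- function(tape, x) {
  tv <- tanh(x$val)
  ad_node(tape, tv, backward = function(nd) ad_acc(x, nd$grad * (1 - tv^2)))
}

ad_exp <- function(tape, x) {
  e <- exp(x$val)
  ad_node(tape, e, backward = function(nd) ad_acc(x, nd$grad * e))
}

ad_log <- function(tape, x) {
  ad_node(tape, log(x$val), backward = function(nd) ad_acc(x, nd$grad / x$val))
}

ad_softplus <- function(tape, x) {
  # numerically stable: log1p(exp(-|x|)) + max(x, 0)
  v <- log1p(exp(-abs(x$val))) + pmax(x$val, 0)
  s <- 1 / (1 + exp(-x$val))
  ad_node(tape, v, backward = function(nd) ad_acc(x, nd$grad * s))
}

ad_pow <- function(tape, x, p) {
  v <- x$val^p
  ad_node(tape, v, backward = function(nd) ad_acc(x, nd$grad * p * x$val^(p - 1)))
}

ad_dropout <- function(tape, x, p, training) {
  if (!training || p <= 0) return(x)
  mask <- (matrix(stats::runif(length(x$val)), nrow(x$val)) >= p) / (1 - p)
  ad_node(tape, x$val * mask, backward = function(nd) ad_acc(x, nd$grad * mask))
}

# ---- fused layers -----------------------------------------------------------

ad_layernorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  xv <- x$val
  mu <- rowMeans(xv)
  xc <- xv - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  g <- as.numeric(gamma$val)
  n <- nrow(xv)
  grep_ <- rep(g, each = n)
  y <- xhat * grep_ + rep(as.numeric(beta$val), each = n)
  ad_node(tape, y, backward = function(nd) {
    dy <- nd$grad
    dxhat <- dy * grep_
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * xhat)
    dx <- inv * (dxhat - m1 - xhat * m2)
    ad_acc(x, dx)
    ad_acc(gamma, matrix(colSums(dy * xhat), 1L))
    ad_acc(beta, matrix(colSums(dy), 1L))
  })
}

ad_softmax_rows <- function(tape, x) {
  m <- x$val
  z <- m - m[cbind(seq_len(nrow(m)), max.col(m, "first"))]
  e <- exp(z)
  p <- e / rowSums(e)
  ad_node(tape, p, backward = function(nd) {
    ad_acc(x, p * (nd$grad - rowSums(nd$grad * p)))
  })
}

# Depthwise causal 1-d convolution over rows (time). x: N x C, w: K x C,
# b: 1 x C. Left-padded with K-1 rows (zeros, or replicated first row) so
# length is preserved and position t only sees positions <= t.
ad_causal_conv1d <- function(tape, x, w, b, pad = c("zero", "replicate")) {
  pad <- match.arg(pad)
  xv <- x$val
  N <- nrow(xv); C <- ncol(xv); K <- nrow(w$val)
  xp <- if (pad == "zero" || K == 1L) rbind(matrix(0, K - 1L, C), xv)
        else rbind(matrix(xv[1L, ], K - 1L, C, byrow = TRUE), xv)
  y <- matrix(as.numeric(b$val), N, C, byrow = TRUE)
  for (k in seq_len(K)) {
    y <- y + xp[k:(k + N - 1L), , drop = FALSE] * rep(w$val[k, ], each = N)
  }
  count_flops(2 * N * C * K)
  ad_node(tape, y, backward = function(nd) {
    dy <- nd$grad
    dxp <- matrix(0, N + K - 1L, C)
    dw <- matrix(0, K, C)
    for (k in seq_len(K)) {
      rows <- k:(k + N - 1L)
      dxp[rows, ] <- dxp[rows, ] + dy * rep(w$val[k, ], each = N)
      dw[k, ] <- colSums(dy * xp[rows, , drop = FALSE])
    }
    dx <- dxp[K:(K + N - 1L), , drop = FALSE]
    if (pad == "replicate" && K > 1L)
      dx[1L, ] <- dx[1L, ] + colSums(dxp[seq_len(K - 1L), , drop = FALSE])
    ad_acc(x, dx)
    ad_acc(w, dw)
    ad_acc(b, matrix(colSums(dy), 1L))
  })
}

# Fused scaled-dot-product attention, single head, dense (rectangular ok).
# q: Nq x d, k/v: Nk x d. Optional additive mask (Nq x Nk). If `record` is an
# environment, the row-stochastic weight matrix is appended to record$maps.
ad_attention_dense <- function(tape, q, k, v, mask = NULL, record = NULL,
                               label = NULL) {
  d <- ncol(q$val)
  sc <- 1 / sqrt(d)
  s <- (q$val %*% t(k$val)) * sc
  if (!is.null(mask)) s <- s + mask
  s <- s - apply(s, 1L, max)
  e <- exp(s)
  p <- e / rowSums(e)
  o <- p %*% v$val
  count_flops(2 * nrow(q$val) * nrow(k$val) * d * 2)
  if (!is.null(record)) {
    record$maps[[length(record$maps) + 1L]] <-
      structure(p, label = label %||% "attention")
  }
  ad_node(tape, o, backward = function(nd) {
    dv <- t(p) %*% nd$grad
    dp <- nd$grad %*% t(v$val)
    ds <- p * (dp - rowSums(dp * p))
    ad_acc(q, (ds %*% k$val) * sc)
    ad_acc(k, (t(ds) %*% q$val) * sc)
    ad_acc(v, dv)
  })
}

# Fused multi-head attention (dense): q is Nq x (heads*hd), k/v Nk x (heads*hd);
# heads are sliced internally so the whole layer is a single tape node.
ad_mha_dense <- function(tape, q, k, v, heads, record = NULL, label = NULL) {
  dk <- ncol(q$val) %/% heads
  sc <- 1 / sqrt(dk)
  Nq <- nrow(q$val); Nk <- nrow(k$val)
  out <- matrix(0, Nq, ncol(q$val))
  ps <- vector("list", heads)
  for (h in seq_len(heads)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    s <- tcrossprod(q$val[, idx, drop = FALSE], k$val[, idx, drop = FALSE]) * sc
    s <- s - s[cbind(seq_len(Nq), max.col(s, "first"))]
    e <- exp(s)
    p <- e / rowSums(e)
    out[, idx] <- p %*% v$val[, idx, drop = FALSE]
    ps[[h]] <- p
    if (!is.null(record))
      record$maps[[length(record$maps) + 1L]] <-
        structure(p, label = sprintf("%s/head%d", label %||% "attention", h))
  }
  count_flops(4 * Nq * Nk * ncol(q$val))
  ad_node(tape, out, backward = function(nd) {
    dq <- matrix(0, Nq, ncol(q$val)); dk_ <- matrix(0, Nk, ncol(q$val))
    dv <- matrix(0, Nk, ncol(q$val))
    for (h in seq_len(heads)) {
      idx <- ((h - 1L) * dk + 1L):(h * dk)
      p <- ps[[h]]
      go <- nd$grad[, idx, drop = FALSE]
      dv[, idx] <- crossprod(p, go)
      dp <- tcrossprod(go, v$val[, idx, drop = FALSE])
      ds <- p * (dp - rowSums(dp * p))
      dq[, idx] <- (ds %*% k$val[, idx, drop = FALSE]) * sc
      dk_[, idx] <- (crossprod(ds, q$val[, idx, drop = FALSE])) * sc
    }
    ad_acc(q, dq); ad_acc(k, dk_); ad_acc(v, dv)
  })
}

# Fused multi-head banded self-attention: per-query-row computation over the
# band only, so elementary-op counts stay linear in N at fixed window.
ad_mha_banded <- function(tape, q, k, v, heads, hw, record = NULL, label = NULL) {
  dk <- ncol(q$val) %/% heads
  sc <- 1 / sqrt(dk)
  N <- nrow(q$val)
  out <- matrix(0, N, ncol(q$val))
  ps <- vector("list", heads)
  idxs <- lapply(seq_len(N), function(i) max(1L, i - hw):min(N, i + hw))
  for (h in seq_len(heads)) {
    cidx <- ((h - 1L) * dk + 1L):(h * dk)
    qh <- q$val[, cidx, drop = FALSE]; kh <- k$val[, cidx, drop = FALSE]
    vh <- v$val[, cidx, drop = FALSE]
    ph <- vector("list", N)
    for (i in seq_len(N)) {
      idx <- idxs[[i]]
      s <- as.numeric(kh[idx, , drop = FALSE] %*% qh[i, ]) * sc
      e <- exp(s - max(s))
      p <- e / sum(e)
      out[i, cidx] <- crossprod(vh[idx, , drop = FALSE], p)
      ph[[i]] <- p
      count_flops(4 * length(idx) * dk)
    }
    ps[[h]] <- ph
    if (!is.null(record)) {
      pm <- matrix(0, N, N)
      for (i in seq_len(N)) pm[i, idxs[[i]]] <- ph[[i]]
      record$maps[[length(record$maps) + 1L]] <-
        structure(pm, label = sprintf("%s/head%d", label %||% "banded", h))
    }
  }
  ad_node(tape, out, backward = function(nd) {
    dq <- matrix(0, N, ncol(q$val)); dk_ <- matrix(0, N, ncol(q$val))
    dv <- matrix(0, N, ncol(q$val))
    for (h in seq_len(heads)) {
      cidx <- ((h - 1L) * dk + 1L):(h * dk)
      qh <- q$val[, cidx, drop = FALSE]; kh <- k$val[, cidx, drop = FALSE]
      vh <- v$val[, cidx, drop = FALSE]
      ph <- ps[[h]]
      for (i in seq_len(N)) {
        idx <- idxs[[i]]; p <- ph[[i]]
        gi <- nd$grad[i, cidx]
        dp <- as.numeric(vh[idx, , drop = FALSE] %*% gi)
        dv[idx, cidx] <- dv[idx, cidx, drop = FALSE] + outer(p, gi)
        ds <- p * (dp - sum(dp * p))
        dq[i, cidx] <- as.numeric(crossprod(kh[idx, , drop = FALSE], ds)) * sc
        dk_[idx, cidx] <- dk_[idx, cidx, drop = FALSE] + outer(ds, qh[i, ]) * sc
      }
    }
    ad_acc(q, dq); ad_acc(k, dk_); ad_acc(v, dv)
  })
}

# Fused selective scan (input-dependent SSM recurrence).
# delta: N x H (positive), B: N x S, C: N x S, u: N x H, A: H x S.
# Per step: Abar[t,h,s] = exp(delta[t,h] A[h,s]); ubar[t,h,s] = delta[t,h] B[t,s] u[t,h]
#           h[t] = Abar[t] * h[t-1] + ubar[t]; y[t,h] = sum_s h[t,h,s] C[t,s]
ad_selective_scan_op <- function(tape, delta, B, C, u, A) {
  dv <- delta$val; Bv <- B$val; Cv <- C$val; uv <- u$val; Av <- A$val
  N <- nrow(dv); H <- ncol(dv); S <- ncol(Bv)
  hs <- vector("list", N)
  Abs <- vector("list", N)
  y <- matrix(0, N, H)
  hprev <- matrix(0, H, S)
  for (t in seq_len(N)) {
    Ab <- exp(dv[t, ] * Av)                       # H x S (delta recycled over cols)
    ub <- (dv[t, ] * uv[t, ]) %o% Bv[t, ]         # H x S
    hprev <- Ab * hprev + ub
    hs[[t]] <- hprev
    Abs[[t]] <- Ab
    y[t, ] <- as.numeric(hprev %*% Cv[t, ])
  }
  count_flops(N * H * S * 6)
  ad_node(tape, y, backward = function(nd) {
    dy <- nd$grad
    dDelta <- matrix(0, N, H); dB <- matrix(0, N, S); dC <- matrix(0, N, S)
    du <- matrix(0, N, H); dA <- matrix(0, H, S)
    dh_next <- matrix(0, H, S)
    zero <- matrix(0, H, S)
    for (t in seq.int(N, 1L)) {
      ht <- hs[[t]]
      dC[t, ] <- as.numeric(crossprod(ht, dy[t, ]))
      dh <- outer(dy[t, ], Cv[t, ]) + dh_next
      hm1 <- if (t > 1L) hs[[t - 1L]] else zero
      Ab <- Abs[[t]]
      dAb <- dh * hm1
      dDelta[t, ] <- rowSums(dAb * Av * Ab) +
        rowSums(dh * outer(uv[t, ], Bv[t, ]))
      dA <- dA + dAb * dv[t, ] * Ab
      dB[t, ] <- as.numeric(crossprod(dh, dv[t, ] * uv[t, ]))
      du[t, ] <- rowSums(dh * (dv[t, ] %o% Bv[t, ]))
      dh_next <- dh * Ab
    }
    ad_acc(delta, dDelta); ad_acc(B, dB); ad_acc(C, dC)
    ad_acc(u, du); ad_acc(A, dA)
  })
}

# Straight-through scale: forward multiplies x by 1 (the hard choice already
# made), backward routes the gradient of the hard branch into the soft
# selection probability `s` (1x1 node).
ad_ste_mul <- function(tape, x, s) {
  ad_node(tape, x$val, backward = function(nd) {
    ad_acc(x, nd$grad)
    ad_acc(s, matrix(sum(nd$grad * x$val), 1L, 1L))
  })
}

# Fused softmax cross-entropy for a single sample. logits: 1 x K node,
# label: integer class index (1-based). Returns scalar node; probs in attr.
ad_ce_loss <- function(tape, logits, label) {
  z <- as.numeric(logits$val)
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  nd <- ad_node(tape, matrix(-log(max(p[label], 1e-12)), 1L, 1L),
                backward = function(nd) {
    g <- p
    g[label] <- g[label] - 1
    ad_acc(logits, matrix(g, 1L) * as.numeric(nd$grad))
  })
  attr(nd, "probs") <- p
  nd
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- parameter utilities ----------------------------------------------------

new_linear <- function(d_in, d_out, sd = 0.05) {
  list(W = ad_param(matrix(stats::rnorm(d_in * d_out, 0, sd), d_in, d_out)),
       b = ad_param(matrix(0, 1L, d_out)))
}

# Fused affine layer x %*% W + b with gradients accumulated directly into the
# persistent parameters (single tape node).
ad_linear <- function(tape, x, lin) {
  W <- lin$W; b <- lin$b
  count_flops(2 * nrow(x$val) * ncol(x$val) * ncol(W$val))
  y <- x$val %*% W$val
  y <- y + rep(as.numeric(b$val), each = nrow(y))
  ad_node(tape, y, backward = function(nd) {
    ad_acc(x, nd$grad %*% t(W$val))
    ad_acc(W, crossprod(x$val, nd$grad))
    ad_acc(b, matrix(colSums(nd$grad), 1L))
  })
}

new_layernorm <- function(d) {
  list(gamma = ad_param(matrix(1, 1L, d)), beta = ad_param(matrix(0, 1L, d)))
}

# Fused layer norm taking the parameter pair directly (single tape node).
ad_ln <- function(tape, x, ln) {
  ad_layernorm(tape, x, ln$gamma, ln$beta)
}

# Flatten a nested list of ad_param objects into a flat named list.
collect_params <- function(x, prefix = "") {
  if (inherits(x, "ad_param")) {
    out <- list(x)
    names(out) <- prefix
    return(out)
  }
  if (is.list(x)) {
    out <- list()
    for (nm in names(x)) {
      out <- c(out, collect_params(x[[nm]], paste0(prefix, if (nzchar(prefix)) "." else "", nm)))
    }
    return(out)
  }
  list()
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

scale_grads <- function(params, s) {
  for (p in params) if (!is.null(p$grad)) p$grad <- p$grad * s
  invisible(NULL)
}

adam_state <- function(params) {
  lapply(params, function(p) list(m = array(0, dim(p$val)),
                                  v = array(0, dim(p$val)), t = 0L))
}

adam_step <- function(params, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (is.null(p$grad)) next
    st <- state[[i]]
    st$t <- st$t + 1L
    st$m <- beta1 * st$m + (1 - beta1) * p$grad
    st$v <- beta2 * st$v + (1 - beta2) * p$grad^2
    mhat <- st$m / (1 - beta1^st$t)
    vhat <- st$v / (1 - beta2^st$t)
    p$val <- p$val - lr * mhat / (sqrt(vhat) + eps)
    state[[i]] <- st
  }
  state
}

# Snapshot / restore parameter values (for checkpoints).
snapshot_params <- function(params) lapply(params, function(p) p$val)

restore_params <- function(params, snap) {
  for (i in seq_along(params)) params[[i]]$val <- snap[[i]]
  invisible(NULL)
}

# Evaluate code with a temporary RNG seed, restoring the previous RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
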