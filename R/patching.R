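#' Split a multivariate sequence into univariate series
#'
#' Column i of the input becomes series i; order is preserved, so binding the
#' returned series column-wise reproduces the input.
#'
#' @param x Numeric matrix, L time steps by M channels.
#' @return List of M numeric vectors of length L.
#' @export
split_modalities <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1L || ncol(x) < 1L) stop("empty matrix")
  lapply(seq_len(ncol(x)), function(i) x[, i])
}

#' Patch specification
#'
#' A sliding-window slicing rule: patch length P, stride Str, and the scale
#' it serves. The patch-to-stride resolution R = P/Str quantifies overlap:
#' the long-range scale uses a lower resolution (coarse, global patterns),
#' the short-range scale a higher one (fine-grained fluctuations); the
#' config validator enforces that ordering.
#'
#' @param P Patch length in time steps (>= 1).
#' @param Str Stride in time steps, 1 <= Str <= P.
#' @param scale "long" or "short".
#' @return A \code{patch_spec} list.
#' @export
patch_spec <- function(P, Str, scale = c("long", "short")) {
  P <- as.integer(P); Str <- as.integer(Str)
  if (Str < 1L || P < Str) stop("need 1 <= Str <= P")
  structure(list(P = P, Str = Str, scale = match.arg(scale)),
            class = "patch_spec")
}

#' Slice a univariate series into overlapping patches
#'
#' Produces N = floor((L - P)/Str) + 1 rows; row k (0-based) is the verbatim
#' slice \code{series[k*Str + 1 .. k*Str + P]}. Trailing steps not covered by
#' a full window are dropped (no padding), which is exactly the regime in
#' which the count formula is an identity.
#'
#' @param series Numeric vector of length L >= P.
#' @param spec A [patch_spec()].
#' @return A \code{patched_series}: list with \code{patches} (N x P matrix),
#'   \code{spec}, and \code{source_length}.
#' @export
make_patches <- function(series, spec) {
  stopifnot(inherits(spec, "patch_spec"))
  L <- length(series)
  if (spec$P > L)
    stop("series length ", L, " shorter than patch length ", spec$P,
         "; need at least ", spec$P, " steps")
  N <- (L - spec$P) %/% spec$Str + 1L
  starts <- (seq_len(N) - 1L) * spec$Str
  patches <- t(vapply(starts, function(s) series[(s + 1L):(s + spec$P)],
                      numeric(spec$P)))
  if (spec$P == 1L) patches <- matrix(patches, ncol = 1L)
  structure(list(patches = patches, spec = spec, source_length = L),
            class = "patched_series")
}

#' Patch-to-stride resolution
#'
#' R = P/Str: the average number of patches covering a time step. Higher
#' values mean denser overlap and finer temporal information.
#' @param spec A [patch_spec()].
#' @return A single number P/Str.
#' @export
pts_resolution <- function(spec) {
  stopifnot(inherits(spec, "patch_spec"))
  spec$P / spec$Str
}
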