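# Multi-scale spatial-spectral information extraction (MSIE) block.
#
# Four parallel branches over an s x s x c feature map, each emitting 64
# channels, merged by element-wise summation:
#   B1: 1x1 conv -> ReLU -> 3x3 average pooling (size preserving)
#   B2: 1x1 conv -> ReLU
#   B3: 1x1 conv -> ReLU, then 1x3 and 3x1 convs in parallel, summed
#   B4: 1x1 conv -> ReLU, then a serial 1x3 -> 3x1 chain; the intermediate
#       (post-1x3) and final (post-3x1) maps are summed
# Every convolution has 64 filters and is followed by ReLU; spatial size is
# preserved throughout.

MSIE_FILTERS <- 64L

# Flatten an s x s x c array to the (s^2, c) row-major token matrix and back.
.flatten_patch <- function(A) {
  d <- dim(A)
  matrix(aperm(A, c(2L, 1L, 3L)), d[1L] * d[2L], d[3L])
}
.unflatten_map <- function(X, s) {
  aperm(array(X, c(s, s, ncol(X))), c(2L, 1L, 3L))
}

#' Initialize MSIE block parameters
#'
#' Allocates the four-branch convolution kernels (64 filters each) with
#' Kaiming-uniform fan-in weights and zero biases.
#'
#' @param in_channels Number of input channels `c`.
#' @param seed Integer seed; the same seed reproduces the same weights.
#' @return A nested list of class `msie_params` holding per-branch `W`/`b`
#'   arrays.
#' @export
init_msie <- function(in_channels, seed = 1L) {
  stopifnot(in_channels >= 1)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  f <- MSIE_FILTERS
  cv <- function(fan_in) list(W = .kaiming(fan_in, f), b = numeric(f))
  p <- list(
    b1 = cv(in_channels),
    b2 = cv(in_channels),
    b3 = list(p1 = cv(in_channels), h = cv(3L * f), v = cv(3L * f)),
    b4 = list(p1 = cv(in_channels), h = cv(3L * f), v = cv(3L * f))
  )
  structure(p, class = "msie_params", in_channels = as.integer(in_channels))
}

.msie_fwd <- function(X, n, s, P) {
  if (ncol(X) != nrow(P$b1$W))
    stop("input has ", ncol(X), " channels but MSIE params expect ",
         nrow(P$b1$W))
  # branch 1
  l1 <- .linear_fwd(X, P$b1$W, P$b1$b, relu = TRUE)
  pl <- .avgpool_fwd(l1$out, n, s)
  # branch 2
  l2 <- .linear_fwd(X, P$b2$W, P$b2$b, relu = TRUE)
  # branch 3: shared 1x1 stem, parallel 1x3 / 3x1
  l3 <- .linear_fwd(X, P$b3$p1$W, P$b3$p1$b, relu = TRUE)
  h3 <- .conv_fwd(l3$out, n, s, "h", P$b3$h$W, P$b3$h$b, relu = TRUE)
  v3 <- .conv_fwd(l3$out, n, s, "v", P$b3$v$W, P$b3$v$b, relu = TRUE)
  # branch 4: 1x1 stem, serial 1x3 -> 3x1, intermediate + final summed
  l4 <- .linear_fwd(X, P$b4$p1$W, P$b4$p1$b, relu = TRUE)
  h4 <- .conv_fwd(l4$out, n, s, "h", P$b4$h$W, P$b4$h$b, relu = TRUE)
  v4 <- .conv_fwd(h4$out, n, s, "v", P$b4$v$W, P$b4$v$b, relu = TRUE)

  out <- pl$out + l2$out + h3$out + v3$out + h4$out + v4$out
  list(out = out,
       cache = list(l1 = l1$cache, pl = pl$cache, l2 = l2$cache,
                    l3 = l3$cache, h3 = h3$cache, v3 = v3$cache,
                    l4 = l4$cache, h4 = h4$cache, v4 = v4$cache))
}

.msie_bwd <- function(cache, dout) {
  # branch 1
  b1 <- .linear_bwd(cache$l1, .avgpool_bwd(cache$pl, dout))
  # branch 2
  b2 <- .linear_bwd(cache$l2, dout)
  # branch 3
  bh3 <- .conv_bwd(cache$h3, dout)
  bv3 <- .conv_bwd(cache$v3, dout)
  b3s <- .linear_bwd(cache$l3, bh3$dX + bv3$dX)
  # branch 4 (dout reaches both the intermediate and the final map)
  bv4 <- .conv_bwd(cache$v4, dout)
  bh4 <- .conv_bwd(cache$h4, dout + bv4$dX)
  b4s <- .linear_bwd(cache$l4, bh4$dX)

  grads <- list(
    b1 = list(W = b1$dW, b = b1$db),
    b2 = list(W = b2$dW, b = b2$db),
    b3 = list(p1 = list(W = b3s$dW, b = b3s$db),
              h = list(W = bh3$dW, b = bh3$db),
              v = list(W = bv3$dW, b = bv3$db)),
    b4 = list(p1 = list(W = b4s$dW, b = b4s$db),
              h = list(W = bh4$dW, b = bh4$db),
              v = list(W = bv4$dW, b = bv4$db))
  )
  list(dX = b1$dX + b2$dX + b3s$dX + b4s$dX, grads = grads)
}

#' MSIE forward pass on a single patch
#'
#' @param x An `s x s x c` numeric array.
#' @param params Parameters from [init_msie()].
#' @return An `s x s x 64` numeric array; spatial size is preserved.
#' @export
msie_forward <- function(x, params) {
  stopifnot(length(dim(x)) == 3)
  s <- dim(x)[1L]
  if (dim(x)[2L] != s) stop("patch must be square")
  X <- .flatten_patch(x)
  .unflatten_map(.msie_fwd(X, 1L, s, params)$out, s)
}

#' Initialize the two-layer standard-convolution substitute
#'
#' The ablation variant that replaces MSIE: two size-preserving 3x3
#' convolutions (c -> 64 -> 64), each followed by ReLU.
#'
#' @inheritParams init_msie
#' @return A list of class `stdconv_params`.
#' @export
init_std_conv <- function(in_channels, seed = 1L) {
  stopifnot(in_channels >= 1)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  f <- MSIE_FILTERS
  p <- list(c1 = list(W = .kaiming(9L * in_channels, f), b = numeric(f)),
            c2 = list(W = .kaiming(9L * f, f), b = numeric(f)))
  structure(p, class = "stdconv_params", in_channels = as.integer(in_channels))
}

.stdconv_fwd <- function(X, n, s, P) {
  if (ncol(X) != nrow(P$c1$W) / 9L)
    stop("input has ", ncol(X), " channels but params expect ",
         nrow(P$c1$W) / 9L)
  c1 <- .conv_fwd(X, n, s, "sq", P$c1$W, P$c1$b, relu = TRUE)
  c2 <- .conv_fwd(c1$out, n, s, "sq", P$c2$W, P$c2$b, relu = TRUE)
  list(out = c2$out, cache = list(c1 = c1$cache, c2 = c2$cache))
}

.stdconv_bwd <- function(cache, dout) {
  g2 <- .conv_bwd(cache$c2, dout)
  g1 <- .conv_bwd(cache$c1, g2$dX)
  list(dX = g1$dX,
       grads = list(c1 = list(W = g1$dW, b = g1$db),
                    c2 = list(W = g2$dW, b = g2$db)))
}

#' Two-layer standard convolution forward pass on a single patch
#'
#' @param x An `s x s x c` numeric array.
#' @param params Parameters from [init_std_conv()].
#' @return An `s x s x 64` numeric array.
#' @export
standard_conv_forward <- function(x, params) {
  stopifnot(length(dim(x)) == 3)
  s <- dim(x)[1L]
  if (dim(x)[2L] != s) stop("patch must be square")
  X <- .flatten_patch(x)
  .unflatten_map(.stdconv_fwd(X, 1L, s, params)$out, s)
}

# Preserve and restore the caller's RNG state around seeded initializers.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
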