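# Semantic-guided attention (SGA) block.
#
# The stage input is flattened row-major to s^2 tokens of width c. Channels
# are gated by sigmoid(w_c), a learnable pixel-weight column w_p is appended
# (token width becomes d = c + 1), and the tokens pass through a
# positional-encoding-free pre-normalized transformer encoder:
#   z   = x_p + MultiHead(LN1(x_p))
#   out = z + MLP(LN2(z)),   MLP = linear(d -> m), GELU, linear(m -> d)
# The last column of the encoded tokens is squashed by a sigmoid and reshaped
# to an s x s spatial weight map, the block's sole product; the map
# multiplicatively gates the main branch (done in the full model).

#' Initialize SGA block parameters
#'
#' @param channels Channel count `c` of the stage input; tokens have width
#'   `d = c + 1` after the pixel-weight column is appended.
#' @param s Patch side (odd); `w_p` has one entry per spatial position.
#' @param mlp_hidden Hidden width of the encoder MLP (default 152).
#' @param heads Number of attention heads (default 1); must divide `c + 1`.
#' @param depth Number of encoder layers (default 1).
#' @param seed Integer seed for the weight initialization.
#' @return A list of class `sga_params`: `w_p`, `w_c`, and per-layer layer
#'   norm, attention, and MLP weights.
#' @export
init_sga <- function(channels, s, mlp_hidden = 152L, heads = 1L,
                     depth = 1L, seed = 1L) {
  stopifnot(channels >= 1, s >= 1, depth >= 1)
  d <- channels + 1L
  if (d %% heads != 0L)
    stop("token width ", d, " is not divisible by heads = ", heads)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  lin <- function(din, dout) list(W = .kaiming(din, dout), b = numeric(dout))
  # Residual output projections (W_O and the second MLP linear) start at
  # reduced scale so the encoder output is near the identity and the sigmoid
  # gate opens near-neutral (~0.5) instead of saturating randomly per token.
  lin_res <- function(din, dout)
    list(W = 0.1 * .kaiming(din, dout), b = numeric(dout))
  layer <- function() list(
    ln1 = list(gamma = rep(1, d), beta = numeric(d)),
    attn = list(Wq = .kaiming(d, d), bq = numeric(d),
                Wk = .kaiming(d, d), bk = numeric(d),
                Wv = .kaiming(d, d), bv = numeric(d),
                Wo = 0.1 * .kaiming(d, d), bo = numeric(d)),
    ln2 = list(gamma = rep(1, d), beta = numeric(d)),
    mlp = c(lin1 = list(lin(d, mlp_hidden)),
            lin2 = list(lin_res(mlp_hidden, d)))
  )
  p <- list(w_p = numeric(s * s), w_c = numeric(channels),
            layers = lapply(seq_len(depth), function(i) layer()))
  structure(p, class = "sga_params", channels = as.integer(channels),
            s = as.integer(s), heads = as.integer(heads))
}

# ---- multi-head attention --------------------------------------------------

.mha_fwd <- function(X, n, s2, A, h) {
  d <- ncol(X)
  dk <- d %/% h
  q <- .linear_fwd(X, A$Wq, A$bq)
  k <- .linear_fwd(X, A$Wk, A$bk)
  v <- .linear_fwd(X, A$Wv, A$bv)
  heads <- vector("list", h)
  concat <- matrix(0, nrow(X), d)
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * dk + 1L):(i * dk)
    at <- .attn_fwd(q$out[, cols, drop = FALSE], k$out[, cols, drop = FALSE],
                    v$out[, cols, drop = FALSE], n, s2)
    concat[, cols] <- at$out
    heads[[i]] <- at$cache
  }
  o <- .linear_fwd(concat, A$Wo, A$bo)
  list(out = o$out,
       cache = list(q = q$cache, k = k$cache, v = v$cache, heads = heads,
                    o = o$cache, h = h, dk = dk, d = d))
}

.mha_bwd <- function(cache, dout) {
  ob <- .linear_bwd(cache$o, dout)
  d <- cache$d; dk <- cache$dk
  dQ <- matrix(0, nrow(dout), d); dK <- dQ; dV <- dQ
  for (i in seq_len(cache$h)) {
    cols <- ((i - 1L) * dk + 1L):(i * dk)
    ab <- .attn_bwd(cache$heads[[i]], ob$dX[, cols, drop = FALSE])
    dQ[, cols] <- ab$dQ; dK[, cols] <- ab$dK; dV[, cols] <- ab$dV
  }
  qb <- .linear_bwd(cache$q, dQ)
  kb <- .linear_bwd(cache$k, dK)
  vb <- .linear_bwd(cache$v, dV)
  list(dX = qb$dX + kb$dX + vb$dX,
       grads = list(Wq = qb$dW, bq = qb$db, Wk = kb$dW, bk = kb$db,
                    Wv = vb$dW, bv = vb$db, Wo = ob$dW, bo = ob$db))
}

# ---- encoder layer ---------------------------------------------------------

.encoder_fwd <- function(X, n, s2, L, h) {
  ln1 <- .ln_fwd(X, L$ln1$gamma, L$ln1$beta)
  mha <- .mha_fwd(ln1$out, n, s2, L$attn, h)
  z <- X + mha$out
  ln2 <- .ln_fwd(z, L$ln2$gamma, L$ln2$beta)
  m1 <- .linear_fwd(ln2$out, L$mlp$lin1$W, L$mlp$lin1$b)
  g <- .gelu_fwd(m1$out)
  m2 <- .linear_fwd(g$out, L$mlp$lin2$W, L$mlp$lin2$b)
  list(out = z + m2$out,
       cache = list(ln1 = ln1$cache, mha = mha$cache, ln2 = ln2$cache,
                    m1 = m1$cache, g = g$cache, m2 = m2$cache))
}

.encoder_bwd <- function(cache, dout) {
  m2b <- .linear_bwd(cache$m2, dout)
  gb <- .gelu_bwd(cache$g, m2b$dX)
  m1b <- .linear_bwd(cache$m1, gb)
  ln2b <- .ln_bwd(cache$ln2, m1b$dX)
  dz <- dout + ln2b$dX
  mhab <- .mha_bwd(cache$mha, dz)
  ln1b <- .ln_bwd(cache$ln1, mhab$dX)
  dX <- dz + ln1b$dX
  grads <- list(
    ln1 = list(gamma = ln1b$dgamma, beta = ln1b$dbeta),
    attn = mhab$grads,
    ln2 = list(gamma = ln2b$dgamma, beta = ln2b$dbeta),
    mlp = list(lin1 = list(W = m1b$dW, b = m1b$db),
               lin2 = list(W = m2b$dW, b = m2b$db))
  )
  list(dX = dX, grads = grads)
}

# ---- full SGA pipeline (batched, internal) --------------------------------

.sga_fwd <- function(X, n, s, P, h = 1L) {
  ch <- length(P$w_c)
  if (ncol(X) != ch)
    stop("input has ", ncol(X), " channels but SGA params expect ", ch)
  N <- nrow(X)
  s2 <- s * s
  d <- ch + 1L
  sc <- .sigmoid(P$w_c)
  Xc <- X * rep(sc, each = N)
  Xp <- cbind(Xc, rep(P$w_p, n), deparse.level = 0L)
  enc <- Xp
  lcaches <- vector("list", length(P$layers))
  for (li in seq_along(P$layers)) {
    e <- .encoder_fwd(enc, n, s2, P$layers[[li]], h)
    enc <- e$out
    lcaches[[li]] <- e$cache
  }
  w <- .sigmoid(enc[, d])
  list(w = w,
       cache = list(X = X, sc = sc, layers = lcaches, w = w, d = d,
                    n = n, s2 = s2, ch = ch))
}

.sga_bwd <- function(cache, dw) {
  d <- cache$d; N <- length(dw)
  dEnc <- matrix(0, N, d)
  dEnc[, d] <- dw * cache$w * (1 - cache$w)
  lgrads <- vector("list", length(cache$layers))
  for (li in rev(seq_along(cache$layers))) {
    eb <- .encoder_bwd(cache$layers[[li]], dEnc)
    dEnc <- eb$dX
    lgrads[[li]] <- eb$grads
  }
  ch <- cache$ch
  dXc <- dEnc[, seq_len(ch), drop = FALSE]
  dwp <- rowsum(dEnc[, d], rep(seq_len(cache$s2), cache$n))[, 1L]
  dX <- dXc * rep(cache$sc, each = N)
  dwc <- colSums(dXc * cache$X) * cache$sc * (1 - cache$sc)
  list(dX = dX,
       grads = list(w_p = dwp, w_c = dwc, layers = lgrads))
}

# ---- user-facing sub-operations -------------------------------------------

#' Gate token channels with a learnable channel weight
#'
#' `x_c[i, j] = sigmoid(w_c[j]) * x[i, j]`, filtering spectral bands.
#'
#' @param x Token matrix (`s^2 x c`).
#' @param w_c Numeric vector of length `c`.
#' @return Gated token matrix of the same shape.
#' @export
channel_gate <- function(x, w_c) {
  x <- as.matrix(x)
  if (length(w_c) != ncol(x))
    stop("w_c has length ", length(w_c), " but x has ", ncol(x), " channels")
  x * rep(.sigmoid(w_c), each = nrow(x))
}

#' Append the pixel-weight column to gated tokens
#'
#' Concatenates `w_p` as the last column, widening tokens from `c` to `c + 1`.
#'
#' @param x_c Token matrix (`s^2 x c`).
#' @param w_p Numeric vector of length `s^2`.
#' @return An `s^2 x (c + 1)` matrix.
#' @export
append_pixel_weight <- function(x_c, w_p) {
  x_c <- as.matrix(x_c)
  if (length(w_p) != nrow(x_c))
    stop("w_p has length ", length(w_p), " but x_c has ", nrow(x_c), " rows")
  cbind(x_c, as.numeric(w_p), deparse.level = 0L)
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V` with a row-wise softmax; every attention row
#' sums to one.
#'
#' @param Q,K,V Numeric matrices with equal row counts; `Q` and `K` share a
#'   width `d_k`.
#' @return A matrix of dim `nrow(Q) x ncol(V)`.
#' @export
scaled_dot_attention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) stop("Q and K widths differ")
  if (nrow(K) != nrow(V)) stop("K and V row counts differ")
  .attn_fwd(Q, K, V, 1L, nrow(Q))$out
}

#' Multi-head self-attention over a token matrix
#'
#' Learned Q/K/V maps, `h` heads of width `d/h`, per-head scaled dot-product
#' attention, concatenation, and the output map `W_O`.
#'
#' @param tokens `n x d` token matrix.
#' @param params List with `Wq, bq, Wk, bk, Wv, bv, Wo, bo` (each map `d x d`).
#' @param h Number of heads; must divide `d`.
#' @return An `n x d` matrix.
#' @export
multi_head_attention <- function(tokens, params, h = 1L) {
  tokens <- as.matrix(tokens)
  d <- ncol(tokens)
  if (d %% h != 0L) stop("token width ", d, " is not divisible by h = ", h)
  .mha_fwd(tokens, 1L, nrow(tokens), params, as.integer(h))$out
}

#' One pre-normalized transformer encoder layer
#'
#' `z = x_p + MultiHead(LN1(x_p)); out = z + MLP(LN2(z))` with a GELU MLP and
#' no positional encoding.
#'
#' @param x_p `s^2 x d` token matrix.
#' @param params One encoder layer: `ln1`, `attn`, `ln2`, `mlp` as produced
#'   by [init_sga()] (`params$layers[[i]]`).
#' @param h Number of attention heads.
#' @return Encoded token matrix, same shape as the input.
#' @export
encoder_block <- function(x_p, params, h = 1L) {
  x_p <- as.matrix(x_p)
  .encoder_fwd(x_p, 1L, nrow(x_p), params, as.integer(h))$out
}

#' Extract the sigmoid spatial weight map from encoded tokens
#'
#' Applies a sigmoid to the last token column and reshapes it row-major to
#' `s x s`; every entry lies strictly inside (0, 1).
#'
#' @param encoded `s^2 x d` encoded token matrix.
#' @param s Patch side.
#' @return An `s x s` matrix in (0, 1).
#' @export
extract_weight_map <- function(encoded, s) {
  encoded <- as.matrix(encoded)
  if (nrow(encoded) != s * s)
    stop("encoded has ", nrow(encoded), " rows; expected s^2 = ", s * s)
  matrix(.sigmoid(encoded[, ncol(encoded)]), s, s, byrow = TRUE)
}

#' SGA forward pass on a single patch
#'
#' Flattens the `s x s x c` stage input row-major to tokens, gates channels,
#' appends the pixel weight, runs the encoder, and extracts the weight map.
#'
#' @param x An `s x s x c` numeric array.
#' @param params Parameters from [init_sga()].
#' @return An `s x s` weight map in (0, 1).
#' @export
sga_forward <- function(x, params) {
  stopifnot(length(dim(x)) == 3)
  s <- dim(x)[1L]
  if (dim(x)[2L] != s) stop("patch must be square")
  if (s != attr(params, "s"))
    stop("patch side ", s, " does not match params (s = ", attr(params, "s"), ")")
  X <- .flatten_patch(x)
  h <- attr(params, "heads")
  w <- .sga_fwd(X, 1L, s, params, if (is.null(h)) 1L else h)$w
  matrix(w, s, s, byrow = TRUE)
}
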