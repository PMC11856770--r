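# Internal neural-network primitives.
#
# Feature maps live as dense matrices of shape (n * s^2, channels): rows are
# sample-major, then row-major over the s x s spatial grid, so token p of
# sample b sits at row (b-1)*s^2 + p with p = (r-1)*s + col. All layers come
# in forward/backward pairs; forwards return list(out, cache) and backwards
# consume (cache, dout). Matrix products go through BLAS; memory-bound steps
# (im2col gathers, scatter-adds, bias+ReLU, pooling, GELU) are C++ kernels.

.nn_cache <- new.env(parent = emptyenv())

# Row-index matrix (N x T) for a set of spatial taps on an s x s grid
# replicated over n samples; out-of-grid sources get index N + 1 (zero cell).
.taps_idx <- function(n, s, kind) {
  key <- paste(n, s, kind, sep = "_")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  taps <- switch(kind,
                 h = list(c(0L, -1L), c(0L, 0L), c(0L, 1L)),
                 v = list(c(-1L, 0L), c(0L, 0L), c(1L, 0L)),
                 sq = {
                   t <- list()
                   for (dr in -1:1) for (dc in -1:1)
                     t[[length(t) + 1L]] <- c(dr, dc)
                   t
                 },
                 stop("unknown tap kind: ", kind))
  s2 <- s * s
  N <- n * s2
  p <- seq_len(s2)
  r <- (p - 1L) %/% s + 1L
  cl <- (p - 1L) %% s + 1L
  off <- rep.int((seq_len(n) - 1L) * s2, rep.int(s2, n))
  idx <- matrix(0L, N, length(taps))
  for (t in seq_along(taps)) {
    sr <- r + taps[[t]][1L]
    sc <- cl + taps[[t]][2L]
    ok <- sr >= 1L & sr <= s & sc >= 1L & sc <= s
    base <- ifelse(ok, (sr - 1L) * s + sc, 0L)
    full <- rep(base, n) + off
    full[rep(!ok, n)] <- N + 1L
    idx[, t] <- as.integer(full)
  }
  .nn_cache[[key]] <- idx
  idx
}

# Dense map over channels (1x1 convolution and fully connected are the
# same), with optionally fused ReLU.
.linear_fwd <- function(X, W, b, relu = FALSE) {
  out <- cpp_add_bias(X %*% W, b, relu)
  list(out = out,
       cache = list(X = X, W = W, out = if (relu) out, relu = relu))
}
.linear_bwd <- function(cache, dout) {
  if (cache$relu) dout <- cpp_relu_bwd(dout, cache$out)
  list(dX = tcrossprod(dout, cache$W),
       dW = crossprod(cache$X, dout),
       db = colSums(dout))
}

# Spatial convolution with centered taps, zero padding, stride 1, via
# im2col. W has dim (T * Cin, Cout), rows tap-major.
.conv_fwd <- function(X, n, s, kind, W, b, relu = FALSE) {
  idx <- .taps_idx(n, s, kind)
  Xcol <- cpp_gather(X, idx)
  out <- cpp_add_bias(Xcol %*% W, b, relu)
  list(out = out,
       cache = list(Xcol = Xcol, idx = idx, W = W, Cin = ncol(X),
                    out = if (relu) out, relu = relu))
}
.conv_bwd <- function(cache, dout) {
  if (cache$relu) dout <- cpp_relu_bwd(dout, cache$out)
  list(dX = cpp_scatter(tcrossprod(dout, cache$W), cache$idx, cache$Cin),
       dW = crossprod(cache$Xcol, dout),
       db = colSums(dout))
}

# 3x3 average pooling, size preserving; the mean is over cells inside the
# grid only (padded cells do not dilute the average).
.avgpool_fwd <- function(X, n, s) {
  idx <- .taps_idx(n, s, "sq")
  r <- cpp_pool_fwd(X, idx)
  list(out = r$out, cache = list(idx = idx, cnt = r$cnt))
}
.avgpool_bwd <- function(cache, dout) {
  cpp_pool_bwd(dout, cache$idx, cache$cnt)
}

.relu_fwd <- function(X) {
  out <- cpp_relu(X)
  list(out = out, cache = out)
}
.relu_bwd <- function(cache, dout) cpp_relu_bwd(dout, cache)

.gelu_fwd <- function(X) list(out = cpp_gelu_fwd(X), cache = X)
.gelu_bwd <- function(cache, dout) cpp_gelu_bwd(dout, cache)

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Layer normalization over the channel dimension of each row.
.ln_fwd <- function(X, gamma, beta, eps = 1e-5) {
  r <- cpp_ln_fwd(X, gamma, beta, eps)
  list(out = r$out, cache = list(xhat = r$xhat, inv = r$inv, gamma = gamma))
}
.ln_bwd <- function(cache, dout) {
  r <- cpp_ln_bwd(dout, cache$xhat, cache$inv, cache$gamma)
  list(dX = r$dX, dgamma = r$dgamma, dbeta = r$dbeta)
}

# Row-wise softmax; a single global shift keeps exp() in range and cancels
# row-wise.
.softmax_rows <- function(S) {
  S <- exp(S - max(S))
  S / rowSums(S)
}

# Scaled dot-product attention over independent token blocks (one per
# sample); Q, K, V are (n * s2, dk). Per-block products run through BLAS in
# the C++ kernel; each softmax row sums to one.
.attn_fwd <- function(Q, K, V, n, s2) {
  r <- cpp_attn_fwd(Q, K, V, n, s2)
  list(out = r$out,
       cache = list(P = r$P, Q = Q, K = K, V = V, n = n, s2 = s2))
}
.attn_bwd <- function(cache, dout) {
  cpp_attn_bwd(dout, cache$P, cache$Q, cache$K, cache$V, cache$n, cache$s2)
}

# Softmax cross-entropy over logits (n x K); labels in 1..K.
.xent_fwd <- function(logits, labels) {
  n <- nrow(logits)
  P <- .softmax_rows(logits)
  picked <- P[cbind(seq_len(n), labels)]
  loss <- -mean(log(pmax(picked, 1e-300)))
  dlogits <- P
  dlogits[cbind(seq_len(n), labels)] <- dlogits[cbind(seq_len(n), labels)] - 1
  list(loss = loss, dlogits = dlogits / n)
}

# ---- nested parameter-list utilities -------------------------------------

.leafmap <- function(x, f) {
  if (is.list(x)) lapply(x, .leafmap, f = f) else f(x)
}
.leafsum <- function(x, f) {
  if (is.list(x)) sum(vapply(x, .leafsum, numeric(1), f = f)) else f(x)
}

.zeros_like <- function(p) .leafmap(p, function(a) a * 0)

# Kaiming-uniform fan-in initialization for a (fan_in, fan_out) weight.
.kaiming <- function(fan_in, fan_out) {
  bound <- sqrt(6 / fan_in)
  matrix(runif(fan_in * fan_out, -bound, bound), fan_in, fan_out)
}

.adam_init <- function(params) {
  list(m = .zeros_like(params), v = .zeros_like(params), t = 0L)
}

.adam_rec <- function(p, g, m, v, lr, t, b1, b2, eps) {
  if (is.list(p)) {
    parts <- Map(.adam_rec, p, g, m, v,
                 MoreArgs = list(lr = lr, t = t, b1 = b1, b2 = b2, eps = eps))
    list(p = lapply(parts, `[[`, "p"),
         m = lapply(parts, `[[`, "m"),
         v = lapply(parts, `[[`, "v"))
  } else {
    m2 <- b1 * m + (1 - b1) * g
    v2 <- b2 * v + (1 - b2) * g * g
    mh <- m2 / (1 - b1^t)
    vh <- v2 / (1 - b2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m2, v = v2)
  }
}

.adam_step <- function(params, grads, state, lr,
                       b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- .adam_rec(params, grads, state$m, state$v, lr, state$t, b1, b2, eps)
  list(params = upd$p, state = list(m = upd$m, v = upd$v, t = state$t))
}
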