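# Independent oracles used across the suite. These deliberately share no code
# with the implementation: plain nested loops and literal index arithmetic.

# Zero-padded 2-D convolution of an s x s x cin array with a centered
# kh x kw kernel, weights given in the package's tap-major layout
# (rows of W: tap-major blocks of cin), optionally followed by ReLU.
naive_conv <- function(x, W, b, kh, kw, relu = TRUE) {
  s <- dim(x)[1L]; cin <- dim(x)[3L]; cout <- ncol(W)
  hr <- (kh - 1L) %/% 2L; hc <- (kw - 1L) %/% 2L
  out <- array(0, c(s, s, cout))
  taps <- expand.grid(dc = -hc:hc, dr = -hr:hr)[, c("dr", "dc")]
  taps <- taps[order(taps$dr, taps$dc), ]
  for (r in 1:s) for (cl in 1:s) for (o in 1:cout) {
    acc <- b[o]
    for (t in seq_len(nrow(taps))) {
      rr <- r + taps$dr[t]; cc <- cl + taps$dc[t]
      if (rr >= 1 && rr <= s && cc >= 1 && cc <= s)
        for (ci in 1:cin)
          acc <- acc + x[rr, cc, ci] * W[(t - 1L) * cin + ci, o]
    }
    out[r, cl, o] <- if (relu) max(acc, 0) else acc
  }
  out
}

# 3x3 average pooling over valid (in-image) cells only, size preserving.
naive_avgpool <- function(x) {
  s <- dim(x)[1L]
  out <- array(0, dim(x))
  for (r in 1:s) for (cl in 1:s) {
    rs <- max(1, r - 1):min(s, r + 1)
    cs <- max(1, cl - 1):min(s, cl + 1)
    for (ch in seq_len(dim(x)[3L]))
      out[r, cl, ch] <- mean(x[rs, cs, ch])
  }
  out
}

# Full MSIE block recomputed from the parameter list with the naive
# primitives above.
naive_msie <- function(x, P) {
  relu1x1 <- function(x, L) naive_conv(x, L$W, L$b, 1L, 1L, relu = TRUE)
  b1 <- naive_avgpool(relu1x1(x, P$b1))
  b2 <- relu1x1(x, P$b2)
  t3 <- relu1x1(x, P$b3$p1)
  b3 <- naive_conv(t3, P$b3$h$W, P$b3$h$b, 1L, 3L) +
    naive_conv(t3, P$b3$v$W, P$b3$v$b, 3L, 1L)
  t4 <- relu1x1(x, P$b4$p1)
  u <- naive_conv(t4, P$b4$h$W, P$b4$h$b, 1L, 3L)
  b4 <- u + naive_conv(u, P$b4$v$W, P$b4$v$b, 3L, 1L)
  b1 + b2 + b3 + b4
}

# Per-query double-loop scaled dot-product attention.
naive_attention <- function(Q, K, V) {
  n <- nrow(Q); dk <- ncol(K)
  out <- matrix(0, n, ncol(V))
  for (i in 1:n) {
    logit <- numeric(n)
    for (j in 1:n) logit[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
    w <- exp(logit - max(logit))
    w <- w / sum(w)
    for (j in 1:n) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

# Mirror-pad the full cube by (s-1)/2 per side (edge-included reflection)
# and crop the window: the pad-then-crop oracle for extract_patch. Assumes
# the pad is no wider than the image.
pad_crop_patch <- function(values, center, s) {
  half <- (s - 1L) %/% 2L
  ax <- function(n) c(rev(seq_len(half)), seq_len(n), n + 1L - seq_len(half))
  padded <- values[ax(dim(values)[1L]), ax(dim(values)[2L]), , drop = FALSE]
  padded[center[1L]:(center[1L] + s - 1L),
         center[2L]:(center[2L] + s - 1L), , drop = FALSE]
}

# Flatten an s x s x c array to tokens by literal index arithmetic
# (token i = (row-1)*s + col, 1-based).
tokens_by_hand <- function(x) {
  s <- dim(x)[1L]; ch <- dim(x)[3L]
  X <- matrix(0, s * s, ch)
  for (r in 1:s) for (cl in 1:s) X[(r - 1L) * s + cl, ] <- x[r, cl, ]
  X
}

# Small labeled scene for training tests.
tiny_scene <- function(rows = 16, cols = 16, bands = 8, k = 2,
                       noise_sd = 0.05, seed = 3) {
  generate_scene(scene_spec(rows, cols, bands, k, noise_sd = noise_sd,
                            unlabeled_fraction = 0.1, seed = seed))
}

# Random confusion matrix with all row sums positive.
random_cm <- function(k, n = 200) {
  cm <- matrix(0L, k, k)
  truth <- sample.int(k, n, replace = TRUE)
  pred <- ifelse(runif(n) < 0.7, truth, sample.int(k, n, replace = TRUE))
  for (i in seq_len(n)) cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
  if (any(rowSums(cm) == 0)) diag(cm) <- diag(cm) + 1L
  cm
}
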