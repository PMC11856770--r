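test_that("channel gating multiplies each column by sigmoid(w_c)", {
  set.seed(41)
  x <- matrix(rnorm(9 * 4), 9, 4)
  expect_equal(channel_gate(x, rep(0, 4)), 0.5 * x)
  expect_equal(channel_gate(x, rep(40, 4)), x, tolerance = 1e-12)
  # two-loop oracle
  w <- rnorm(4)
  got <- channel_gate(x, w)
  for (i in 1:9) for (j in 1:4)
    expect_equal(got[i, j], x[i, j] / (1 + exp(-w[j])), tolerance = 1e-12)
  expect_error(channel_gate(x, rep(0, 3)), "length")
})

test_that("the pixel-weight column is appended last and is invertible", {
  x <- matrix(1:8, 4, 2)
  wp <- c(0.1, 0.2, 0.3, 0.4)
  xp <- append_pixel_weight(x, wp)
  expect_equal(dim(xp), c(4L, 3L))
  expect_equal(xp[, 3], wp)
  expect_equal(xp[, 1:2], x, ignore_attr = TRUE)
  expect_equal(append_pixel_weight(x, rep(0, 4))[, 3], rep(0, 4))
  expect_equal(xp[, -3], x, ignore_attr = TRUE)   # drop recovers x exactly
  expect_error(append_pixel_weight(x, 1:3), "length")
})

test_that("scaled dot-product attention matches its limits and the loop oracle", {
  set.seed(42)
  # single token: softmax of a scalar is 1, output = V
  V1 <- matrix(rnorm(3), 1)
  expect_equal(scaled_dot_attention(matrix(rnorm(2), 1), matrix(rnorm(2), 1),
                                    V1), V1)
  # all logits equal (Q = 0): uniform weights, column means of V
  V <- matrix(rnorm(5 * 3), 5)
  got <- scaled_dot_attention(matrix(0, 5, 2), matrix(rnorm(10), 5), V)
  for (i in 1:5) expect_equal(got[i, ], colMeans(V), tolerance = 1e-12)
  # n = 5, dk = 3 random instance vs the double loop
  Q <- matrix(rnorm(15), 5); K <- matrix(rnorm(15), 5); Vv <- matrix(rnorm(15), 5)
  expect_equal(scaled_dot_attention(Q, K, Vv), naive_attention(Q, K, Vv),
               tolerance = 1e-6)
  expect_error(scaled_dot_attention(Q, K[, 1:2], Vv), "widths")
})

test_that("attention rows are stochastic: identity V returns the weight matrix", {
  set.seed(43)
  n <- 7
  P <- scaled_dot_attention(matrix(rnorm(n * 3), n), matrix(rnorm(n * 3), n),
                            diag(n))
  expect_equal(rowSums(P), rep(1, n), tolerance = 1e-6)
  expect_true(all(P > 0))
})

test_that("multi-head attention composes the three sub-operations", {
  set.seed(44)
  d <- 6; n <- 8
  tok <- matrix(rnorm(n * d), n)
  idp <- list(Wq = diag(d), bq = numeric(d), Wk = diag(d), bk = numeric(d),
              Wv = diag(d), bv = numeric(d), Wo = diag(d), bo = numeric(d))
  expect_equal(multi_head_attention(tok, idp, h = 1),
               scaled_dot_attention(tok, tok, tok), tolerance = 1e-12)

  # h = 1 random parameters: manual composition via the sub-operations
  rp <- list(Wq = matrix(rnorm(d * d), d), bq = rnorm(d),
             Wk = matrix(rnorm(d * d), d), bk = rnorm(d),
             Wv = matrix(rnorm(d * d), d), bv = rnorm(d),
             Wo = matrix(rnorm(d * d), d), bo = rnorm(d))
  add_b <- function(M, b) sweep(M, 2, b, "+")
  manual <- add_b(scaled_dot_attention(add_b(tok %*% rp$Wq, rp$bq),
                                       add_b(tok %*% rp$Wk, rp$bk),
                                       add_b(tok %*% rp$Wv, rp$bv)) %*% rp$Wo,
                  rp$bo)
  expect_equal(multi_head_attention(tok, rp, h = 1), manual,
               tolerance = 1e-10)

  # zero value map and zero biases: zero pre-W_O output, so output = 0
  zp <- rp
  zp$Wv <- zp$Wv * 0; zp$bv <- zp$bv * 0; zp$bo <- zp$bo * 0
  expect_true(all(multi_head_attention(tok, zp, h = 1) == 0))

  # h = 2 equals per-head composition on column blocks
  got2 <- multi_head_attention(tok, rp, h = 2)
  Q <- add_b(tok %*% rp$Wq, rp$bq); K <- add_b(tok %*% rp$Wk, rp$bk)
  V <- add_b(tok %*% rp$Wv, rp$bv)
  cc <- cbind(scaled_dot_attention(Q[, 1:3], K[, 1:3], V[, 1:3]),
              scaled_dot_attention(Q[, 4:6], K[, 4:6], V[, 4:6]))
  expect_equal(got2, add_b(cc %*% rp$Wo, rp$bo), tolerance = 1e-10)
  expect_error(multi_head_attention(tok, rp, h = 4), "divisible")
})

test_that("the encoder layer is a pre-norm residual block without positions", {
  set.seed(45)
  d <- 5; n <- 9
  xp <- matrix(rnorm(n * d), n)
  params <- init_sga(d - 1L, 3L, mlp_hidden = 7L, seed = 1)
  layer <- params$layers[[1]]

  # all weights zero, LN scale 1 shift 0: residuals only
  zl <- rapply(layer, function(a) a * 0, how = "replace")
  zl$ln1$gamma <- rep(1, d); zl$ln2$gamma <- rep(1, d)
  expect_equal(encoder_block(xp, zl), xp, ignore_attr = TRUE)

  # permutation equivariance (no positional encoding anywhere)
  perm <- sample(n)
  expect_equal(encoder_block(xp, layer)[perm, ],
               encoder_block(xp[perm, ], layer), tolerance = 1e-10)

  # depth contract: the default configuration has exactly one encoder layer
  expect_length(params$layers, 1L)
  expect_length(init_sga(4L, 3L, depth = 2L)$layers, 2L)
})

test_that("weight maps come from the last column, reshaped row-major, in (0,1)", {
  set.seed(46)
  s <- 3
  enc <- matrix(rnorm(s * s * 4), s * s, 4)
  wm <- extract_weight_map(enc, s)
  expect_true(all(wm > 0 & wm < 1))
  # index-arithmetic oracle: token i -> (row, col) = ((i-1) %/% s + 1, (i-1) %% s + 1)
  for (i in seq_len(s * s))
    expect_equal(wm[(i - 1) %/% s + 1, (i - 1) %% s + 1],
                 1 / (1 + exp(-enc[i, 4])))
  expect_equal(extract_weight_map(matrix(0, 9, 2), 3),
               matrix(0.5, 3, 3))
  expect_lt(max(extract_weight_map(matrix(-50, 9, 2), 3)), 1e-20)
  expect_error(extract_weight_map(matrix(0, 8, 2), 3), "s\\^2")
})

test_that("sga_forward equals the manual composition of its four stages", {
  set.seed(47)
  s <- 5; ch <- 6
  x <- array(rnorm(s * s * ch), c(s, s, ch))
  params <- init_sga(ch, s, mlp_hidden = 9L, seed = 7)
  params$w_p <- rnorm(s * s)
  params$w_c <- rnorm(ch)

  wm <- sga_forward(x, params)
  expect_equal(dim(wm), c(s, s))
  expect_true(all(wm > 0 & wm < 1))
  expect_identical(sga_forward(x, params), wm)   # determinism

  X <- tokens_by_hand(x)
  enc <- encoder_block(append_pixel_weight(channel_gate(X, params$w_c),
                                           params$w_p),
                       params$layers[[1]], h = 1)
  expect_equal(wm, extract_weight_map(enc, s), tolerance = 1e-12)
})
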