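test_that("the model builds with the documented structure and is seed-deterministic", {
  cfg <- sgtn_config(bands = 200, n_classes = 16, s = 13, seed = 5)
  m <- build_sgtn(cfg)
  expect_equal(dim(m$params$red$W), c(200L, 64L))
  expect_equal(nrow(m$params$stages[[1]]$main$b1$W), 64L)  # stage-1 MSIE in=64
  expect_equal(dim(m$params$fc1$W), c(64L, 32L))
  expect_equal(dim(m$params$fc2$W), c(32L, 16L))
  expect_identical(unlist(build_sgtn(cfg)$params), unlist(m$params))

  nosga <- build_sgtn(sgtn_config(200, 16, 13, use_sga = FALSE))
  expect_null(nosga$params$stages[[1]]$sga)

  expect_error(sgtn_config(200, 16, s = 12), "odd")
  expect_error(sgtn_config(0, 16), "bands")
})

test_that("parameter counts equal an independent shape-by-shape summation", {
  inventory <- function(bands, k, s, m = 152) {
    red <- bands * 64 + 64
    msie <- 2 * (64 * 64 + 64) + 2 * ((64 * 64 + 64) + 2 * (3 * 64 * 64 + 64))
    d <- 65
    sga <- s^2 + 64 + 2 * (d + d) + 4 * (d * d + d) +
      (d * m + m) + (m * d + d)
    fc <- (64 * 32 + 32) + (32 * k + k)
    red + 2 * msie + 2 * sga + fc
  }
  ip <- build_sgtn(sgtn_config(200, 16, 13))
  sa <- build_sgtn(sgtn_config(204, 16, 15))
  pu <- build_sgtn(sgtn_config(103, 9, 15))
  expect_equal(count_parameters(ip), inventory(200, 16, 13))
  expect_equal(count_parameters(sa), inventory(204, 16, 15))
  expect_equal(count_parameters(pu), inventory(103, 9, 15))

  # the count depends on the seed not at all, and on s only through w_p
  expect_equal(count_parameters(build_sgtn(sgtn_config(200, 16, 13, seed = 99))),
               count_parameters(ip))
  expect_equal(count_parameters(build_sgtn(sgtn_config(200, 16, 15))) -
                 count_parameters(ip), 2L * (15L^2 - 13L^2))
  # a single linear map 3 -> 2 with bias has 8 scalars
  expect_equal(3 * 2 + 2, 8)
})

test_that("forward pass is finite, deterministic, and SGA-neutral when the map is one", {
  set.seed(51)
  cfg <- sgtn_config(bands = 6, n_classes = 4, s = 5, mlp_hidden = 11,
                     seed = 2)
  m <- build_sgtn(cfg)
  x <- array(rnorm(5 * 5 * 6), c(5, 5, 6))
  lg <- sgtn_forward(x, m)
  expect_length(lg, 4L)
  expect_true(all(is.finite(lg)))
  expect_identical(sgtn_forward(x, m), lg)

  # disabling SGA equals forcing an (almost exactly) all-ones weight map
  m_no <- build_sgtn(sgtn_config(6, 4, 5, mlp_hidden = 11, use_sga = FALSE,
                                 seed = 2))
  m_ones <- m
  for (k in 1:2) {
    m_ones$params$stages[[k]]$sga$layers[[1]] <-
      rapply(m$params$stages[[k]]$sga$layers[[1]], function(a) a * 0,
             how = "replace")
    m_ones$params$stages[[k]]$sga$layers[[1]]$ln1$gamma <- rep(1, 65)
    m_ones$params$stages[[k]]$sga$layers[[1]]$ln2$gamma <- rep(1, 65)
    m_ones$params$stages[[k]]$sga$w_p <- rep(50, 25)  # sigmoid ~ 1
  }
  expect_equal(sgtn_forward(x, m_no), sgtn_forward(x, m_ones),
               tolerance = 1e-10)

  expect_error(sgtn_forward(array(0, c(5, 5, 7)), m), "bands")
  expect_error(sgtn_forward(array(0, c(7, 7, 6)), m), "side")
})

test_that("forward equals the manual composition reduction -> stages -> pooling -> head", {
  set.seed(52)
  cfg <- sgtn_config(bands = 3, n_classes = 3, s = 5, mlp_hidden = 7,
                     seed = 9)
  m <- build_sgtn(cfg)
  x <- array(rnorm(5 * 5 * 3), c(5, 5, 3))

  p <- m$params
  relu <- function(a) pmax(a, 0)
  # spectral reduction on each pixel spectrum
  x0 <- array(0, c(5, 5, 64))
  for (r in 1:5) for (cl in 1:5)
    x0[r, cl, ] <- relu(drop(x[r, cl, ] %*% p$red$W) + p$red$b)
  stage <- function(xk, st) {
    main <- msie_forward(xk, st$main)
    wm <- sga_forward(xk, st$sga)
    for (ch in seq_len(dim(main)[3])) main[, , ch] <- main[, , ch] * wm
    main
  }
  x1 <- stage(x0, p$stages[[1]])
  x2 <- stage(x1, p$stages[[2]])
  pooled <- apply(x2, 3, mean)
  logits <- drop(relu(drop(pooled %*% p$fc1$W) + p$fc1$b) %*% p$fc2$W) +
    p$fc2$b
  expect_equal(sgtn_forward(x, m), logits, tolerance = 1e-8)
})

test_that("analytic gradients match central finite differences", {
  set.seed(53)
  cfg <- sgtn_config(bands = 3, n_classes = 2, s = 3, mlp_hidden = 7,
                     seed = 3)
  model <- build_sgtn(cfg)
  n <- 2L
  X <- matrix(rnorm(n * 9 * 3), n * 9, 3)
  labels <- c(1L, 2L)

  loss_fn <- function(params) {
    mm <- model; mm$params <- params
    fwd <- sgtn:::.sgtn_fwd(X, n, mm)
    sgtn:::.xent_fwd(fwd$logits, labels)$loss
  }
  fwd <- sgtn:::.sgtn_fwd(X, n, model)
  ce <- sgtn:::.xent_fwd(fwd$logits, labels)
  grads <- sgtn:::.sgtn_bwd(fwd$cache, ce$dlogits, model)$grads

  paths <- function(x, pre = character()) {
    if (is.list(x))
      unlist(lapply(names(x), function(nm) paths(x[[nm]], c(pre, nm))),
             recursive = FALSE)
    else list(pre)
  }
  get_leaf <- function(x, p) { for (k in p) x <- x[[k]]; x }
  set_leaf <- function(x, p, v) {
    if (length(p) == 1) { x[[p]] <- v; return(x) }
    x[[p[1]]] <- set_leaf(x[[p[1]]], p[-1], v)
    x
  }
  eps <- 1e-5
  for (p in paths(model$params)) {
    leaf <- get_leaf(model$params, p)
    g <- get_leaf(grads, p)
    for (i in sample(length(leaf), min(2, length(leaf)))) {
      lp <- leaf; lp[i] <- lp[i] + eps
      lm <- leaf; lm[i] <- lm[i] - eps
      num <- (loss_fn(set_leaf(model$params, p, lp)) -
                loss_fn(set_leaf(model$params, p, lm))) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-4,
                   label = paste("grad", paste(p, collapse = "/"), i))
    }
  }
})

test_that("predict_label takes the argmax with low-index tie breaking", {
  expect_equal(predict_label(c(0.1, 2.0, -1)), 2L)
  expect_equal(predict_label(rep(0.5, 4)), 1L)
  set.seed(54)
  for (i in 1:20) {
    lg <- rnorm(6)
    best <- 1L
    for (j in 2:6) if (lg[j] > lg[best]) best <- j   # linear-scan oracle
    expect_equal(predict_label(lg), best)
  }
  expect_error(predict_label(c(1, NaN)), "NaN")
})

test_that("checkpoints round-trip the configuration and parameters", {
  dir <- withr::local_tempdir()
  cfg <- sgtn_config(bands = 4, n_classes = 3, s = 3, mlp_hidden = 7, seed = 6)
  m <- build_sgtn(cfg)
  path <- file.path(dir, "model.rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_equal(m2$config, m$config)
  x <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  expect_identical(sgtn_forward(x, m2), sgtn_forward(x, m))
  saveRDS(list(a = 1), file.path(dir, "junk.rds"))
  expect_error(load_checkpoint(file.path(dir, "junk.rds")), "checkpoint")
})
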