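# Full SGTN assembly: 1x1 spectral reduction to 64 channels, two stages of
# MSIE gated by the SGA weight map (element-wise multiplication, one s x s
# map per stage broadcast over all channels), global average pooling, and a
# two-layer FC head (64 -> 32 -> n_classes).

#' Model configuration
#'
#' @param bands Input spectral band count.
#' @param n_classes Number of classes (labels 1..n_classes).
#' @param s Patch side, odd (defaults per benchmark: 13 for IP, 15 for SA/PU).
#' @param use_msie If `FALSE`, the main branch is the two-layer standard
#'   3x3 convolution ablation variant.
#' @param use_sga If `FALSE`, no attention branch is allocated and the stage
#'   output is the main branch unchanged (equivalent to an all-ones map).
#' @param heads Attention heads (default 1).
#' @param depth Encoder depth (default 1).
#' @param mlp_hidden Encoder MLP hidden width (default 152).
#' @param seed Integer seed controlling all weight initialization.
#' @return A list of class `sgtn_config`.
#' @export
sgtn_config <- function(bands, n_classes, s = 13L, use_msie = TRUE,
                        use_sga = TRUE, heads = 1L, depth = 1L,
                        mlp_hidden = 152L, seed = 1L) {
  bands <- as.integer(bands); n_classes <- as.integer(n_classes)
  s <- as.integer(s)
  if (bands < 1L) stop("bands must be >= 1")
  if (n_classes < 1L) stop("n_classes must be >= 1")
  if (s < 1L || s %% 2L == 0L) stop("patch side s must be odd and >= 1")
  structure(list(bands = bands, n_classes = n_classes, s = s,
                 use_msie = isTRUE(use_msie), use_sga = isTRUE(use_sga),
                 heads = as.integer(heads), depth = as.integer(depth),
                 mlp_hidden = as.integer(mlp_hidden),
                 reduction_filters = 64L, fc_hidden = 32L,
                 seed = as.integer(seed)),
            class = "sgtn_config")
}

#' Build an SGTN model with seeded deterministic initialization
#'
#' @param config A [sgtn_config()].
#' @return A list of class `sgtn_model` with elements `config` and `params`.
#' @export
build_sgtn <- function(config) {
  stopifnot(inherits(config, "sgtn_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  f <- config$reduction_filters
  red <- list(W = .kaiming(config$bands, f), b = numeric(f))
  fc1 <- list(W = .kaiming(f, config$fc_hidden), b = numeric(config$fc_hidden))
  fc2 <- list(W = .kaiming(config$fc_hidden, config$n_classes),
              b = numeric(config$n_classes))
  sub <- sample.int(.Machine$integer.max - 1L, 4L)
  stage <- function(k) {
    main <- if (config$use_msie) init_msie(f, seed = sub[k])
            else init_std_conv(f, seed = sub[k])
    st <- list(main = main)
    if (config$use_sga)
      st$sga <- init_sga(f, config$s, mlp_hidden = config$mlp_hidden,
                         heads = config$heads, depth = config$depth,
                         seed = sub[k + 2L])
    st
  }
  params <- list(red = red, stages = list(stage(1L), stage(2L)),
                 fc1 = fc1, fc2 = fc2)
  structure(list(config = config, params = params), class = "sgtn_model")
}

# Batched forward over a token matrix X of dim (n * s^2, bands).
.sgtn_fwd <- function(X, n, model) {
  cfg <- model$config; p <- model$params
  s <- cfg$s; s2 <- s * s
  red <- .linear_fwd(X, p$red$W, p$red$b, relu = TRUE)
  x <- red$out
  stages <- vector("list", 2L)
  for (k in 1:2) {
    st <- p$stages[[k]]
    main <- if (cfg$use_msie) .msie_fwd(x, n, s, st$main)
            else .stdconv_fwd(x, n, s, st$main)
    sc <- list(main = main$cache, x_in = x, main_out = main$out)
    if (cfg$use_sga) {
      sg <- .sga_fwd(x, n, s, st$sga, cfg$heads)
      x <- main$out * sg$w
      sc$sga <- sg$cache
      sc$w <- sg$w
    } else {
      x <- main$out
    }
    stages[[k]] <- sc
  }
  grp <- rep(seq_len(n), each = s2)
  pooled <- rowsum(x, grp) / s2
  f1 <- .linear_fwd(pooled, p$fc1$W, p$fc1$b, relu = TRUE)
  f2 <- .linear_fwd(f1$out, p$fc2$W, p$fc2$b)
  list(logits = f2$out,
       cache = list(red = red$cache, stages = stages,
                    f1 = f1$cache, f2 = f2$cache, n = n, s2 = s2))
}

.sgtn_bwd <- function(cache, dlogits, model) {
  cfg <- model$config
  n <- cache$n; s2 <- cache$s2
  f2b <- .linear_bwd(cache$f2, dlogits)
  f1b <- .linear_bwd(cache$f1, f2b$dX)
  dx <- f1b$dX[rep(seq_len(n), each = s2), , drop = FALSE] / s2
  stage_grads <- vector("list", 2L)
  for (k in 2:1) {
    sc <- cache$stages[[k]]
    if (cfg$use_sga) {
      dmain <- dx * sc$w
      dw <- rowSums(dx * sc$main_out)
      sgb <- .sga_bwd(sc$sga, dw)
    } else {
      dmain <- dx
      sgb <- NULL
    }
    mb <- if (cfg$use_msie) .msie_bwd(sc$main, dmain)
          else .stdconv_bwd(sc$main, dmain)
    dx <- mb$dX
    if (!is.null(sgb)) dx <- dx + sgb$dX
    g <- list(main = mb$grads)
    if (!is.null(sgb)) g$sga <- sgb$grads
    stage_grads[[k]] <- g
  }
  redb <- .linear_bwd(cache$red, dx)
  list(grads = list(red = list(W = redb$dW, b = redb$db),
                    stages = stage_grads,
                    fc1 = list(W = f1b$dW, b = f1b$db),
                    fc2 = list(W = f2b$dW, b = f2b$db)))
}

#' SGTN forward pass on a single patch
#'
#' @param patch An `s x s x bands` numeric array matching the model config.
#' @param model A built [build_sgtn()] model.
#' @return Numeric logit vector of length `n_classes` (softmax is applied
#'   only inside the loss and metrics).
#' @export
sgtn_forward <- function(patch, model) {
  stopifnot(inherits(model, "sgtn_model"), length(dim(patch)) == 3)
  cfg <- model$config
  if (dim(patch)[1L] != cfg$s || dim(patch)[2L] != cfg$s)
    stop("patch side does not match model config (s = ", cfg$s, ")")
  if (dim(patch)[3L] != cfg$bands)
    stop("patch has ", dim(patch)[3L], " bands; model expects ", cfg$bands)
  X <- .flatten_patch(patch)
  drop(.sgtn_fwd(X, 1L, model)$logits)
}

#' Count trainable parameters
#'
#' Sums every trainable scalar: convolution and linear weights and biases,
#' layer-norm scales and shifts, and the SGA pixel and channel weights.
#'
#' @param model A built `sgtn_model`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "sgtn_model"))
  as.integer(.leafsum(model$params, length))
}

#' Predicted class from logits
#'
#' Argmax with ties broken toward the lowest class index.
#'
#' @param logits Numeric vector of finite logits.
#' @return Integer class label (1-based).
#' @export
predict_label <- function(logits) {
  if (anyNA(logits) || any(is.nan(logits))) stop("logits contain NaN/NA")
  which.max(logits)
}

#' Save / load a model checkpoint
#'
#' A single-file archive of the named parameter arrays with the model
#' configuration embedded as JSON.
#'
#' @param model A `sgtn_model`.
#' @param path File path for the checkpoint.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `sgtn_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "sgtn_model"))
  obj <- list(format = "sgtn-checkpoint-1",
              config_json = jsonlite::toJSON(unclass(model$config),
                                             auto_unbox = TRUE),
              params = model$params)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "sgtn-checkpoint-1"))
    stop("not an sgtn checkpoint: ", path)
  cj <- jsonlite::fromJSON(obj$config_json)
  config <- sgtn_config(bands = cj$bands, n_classes = cj$n_classes, s = cj$s,
                        use_msie = cj$use_msie, use_sga = cj$use_sga,
                        heads = cj$heads, depth = cj$depth,
                        mlp_hidden = cj$mlp_hidden, seed = cj$seed)
  structure(list(config = config, params = obj$params), class = "sgtn_model")
}
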