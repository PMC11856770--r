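# Training loop (mini-batch Adam on softmax cross-entropy), confusion-matrix
# metrics (OA / AA / Cohen's kappa), repeated-experiment summaries, and
# full-scene classification maps.

#' Training hyperparameters
#'
#' Defaults follow the reference protocol: cross-entropy loss, Adam, learning
#' rate 0.001, batch size 64, 100 epochs.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param epochs Number of passes over the training set.
#' @param seed Integer seed controlling shuffling (and, in
#'   [repeat_experiment()], split membership and initialization).
#' @return A list of class `train_spec`.
#' @export
train_spec <- function(learning_rate = 0.001, batch_size = 64L,
                       epochs = 100L, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(loss = "cross-entropy", optimizer = "adam",
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_spec")
}

.batch_rows <- function(idx, s2) {
  rep((idx - 1L) * s2, each = s2) + rep.int(seq_len(s2), length(idx))
}

# Batched class predictions for a patch set.
.predict_set <- function(model, ps, chunk = 256L) {
  preds <- integer(ps$n)
  s2 <- ps$s * ps$s
  for (start in seq(1L, ps$n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, ps$n)
    Xb <- ps$x[.batch_rows(idx, s2), , drop = FALSE]
    logits <- .sgtn_fwd(Xb, length(idx), model)$logits
    preds[idx] <- max.col(logits, ties.method = "first")
  }
  preds
}

#' Train an SGTN model
#'
#' Mini-batch Adam on cross-entropy for `spec$epochs` passes; per-epoch mean
#' training loss and validation OA are recorded, and the parameters with the
#' best validation OA are returned (final parameters if no validation set).
#' Fully reproducible under `spec$seed`.
#'
#' @param model A built [build_sgtn()] model.
#' @param train_set,val_set [make_patch_set()] objects (`val_set` optional).
#' @param spec A [train_spec()].
#' @return `list(model =, history =)`; `history` is a data frame with
#'   `epoch`, `train_loss`, `val_oa`.
#' @export
train_sgtn <- function(model, train_set, val_set = NULL, spec = train_spec()) {
  stopifnot(inherits(model, "sgtn_model"), inherits(train_set, "patch_set"),
            inherits(spec, "train_spec"))
  if (train_set$n == 0L) stop("empty training set")
  k <- model$config$n_classes
  if (any(train_set$labels < 1L | train_set$labels > k))
    stop("training labels outside 1..", k)
  if (train_set$channels != model$config$bands)
    stop("patch set has ", train_set$channels, " channels; model expects ",
         model$config$bands)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)
  s2 <- train_set$s * train_set$s
  state <- .adam_init(model$params)
  history <- data.frame(epoch = seq_len(spec$epochs), train_loss = NA_real_,
                        val_oa = NA_real_)
  best <- list(oa = -Inf, params = model$params)
  for (ep in seq_len(spec$epochs)) {
    perm <- sample.int(train_set$n)
    losses <- c()
    for (start in seq(1L, train_set$n, by = spec$batch_size)) {
      idx <- perm[start:min(start + spec$batch_size - 1L, train_set$n)]
      Xb <- train_set$x[.batch_rows(idx, s2), , drop = FALSE]
      fwd <- .sgtn_fwd(Xb, length(idx), model)
      ce <- .xent_fwd(fwd$logits, train_set$labels[idx])
      losses <- c(losses, ce$loss)
      bwd <- .sgtn_bwd(fwd$cache, ce$dlogits, model)
      upd <- .adam_step(model$params, bwd$grads, state, spec$learning_rate)
      model$params <- upd$params
      state <- upd$state
    }
    history$train_loss[ep] <- mean(losses)
    if (!is.null(val_set) && val_set$n > 0L) {
      oa <- mean(.predict_set(model, val_set) == val_set$labels)
      history$val_oa[ep] <- oa
      if (oa > best$oa) best <- list(oa = oa, params = model$params)
    }
  }
  if (!is.null(val_set) && val_set$n > 0L) model$params <- best$params
  list(model = model, history = history)
}

#' Evaluate a model on a labeled patch set
#'
#' @param model A trained `sgtn_model`.
#' @param test_set A [make_patch_set()] object.
#' @return A `k x k` integer confusion matrix, rows = true class, columns =
#'   predicted class.
#' @export
evaluate <- function(model, test_set) {
  stopifnot(inherits(model, "sgtn_model"), inherits(test_set, "patch_set"))
  if (test_set$n == 0L) stop("empty test set")
  k <- model$config$n_classes
  preds <- .predict_set(model, test_set)
  cm <- table(factor(test_set$labels, levels = seq_len(k)),
              factor(preds, levels = seq_len(k)))
  m <- matrix(as.integer(cm), k, k)
  dimnames(m) <- list(true = seq_len(k), predicted = seq_len(k))
  m
}

#' Overall accuracy, average accuracy, and Cohen's kappa
#'
#' `overall_accuracy` is trace/total; `average_accuracy` is the unweighted
#' mean of per-class recalls (classes with empty rows are excluded with a
#' warning); `kappa_coefficient` is `(p_o - p_e) / (1 - p_e)` with `p_e` from
#' the row/column marginals.
#'
#' @param cm A square confusion matrix of counts (rows = true).
#' @return A single numeric value.
#' @export
overall_accuracy <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix is empty")
  sum(diag(cm)) / total
}

#' @rdname overall_accuracy
#' @export
average_accuracy <- function(cm) {
  cm <- as.matrix(cm)
  if (sum(cm) <= 0) stop("confusion matrix is empty")
  rs <- rowSums(cm)
  if (any(rs == 0)) {
    warning("classes with no test samples excluded from AA: ",
            paste(which(rs == 0), collapse = ", "))
  }
  keep <- rs > 0
  mean(diag(cm)[keep] / rs[keep])
}

#' @rdname overall_accuracy
#' @export
kappa_coefficient <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix is empty")
  p_o <- sum(diag(cm)) / total
  p_e <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (p_e >= 1) {
    if (p_o == 1) return(1)
    stop("kappa undefined: expected agreement is 1 but observed is not")
  }
  (p_o - p_e) / (1 - p_e)
}

.split_to_sets <- function(cube, gt, split, s) {
  list(train = make_patch_set(cube, gt, split_subset(split, "train"), s),
       val = make_patch_set(cube, gt, split_subset(split, "val"), s),
       test = make_patch_set(cube, gt, split_subset(split, "test"), s))
}

#' Repeat the full experiment with redrawn splits
#'
#' Each repeat redraws the stratified split and reinitializes the model under
#' its own seed, then trains and evaluates; reports mean and standard
#' deviation of OA/AA/kappa and of per-class accuracies over the repeats.
#'
#' @param cube,gt The scene.
#' @param config A [sgtn_config()].
#' @param tspec A [train_spec()].
#' @param train_frac,val_frac Split fractions.
#' @param n_repeats Number of repeats (default 5).
#' @param seeds Optional integer vector of per-repeat seeds (defaults to
#'   `tspec$seed + 0:(n_repeats-1)`).
#' @return A list of class `repeat_summary`: `runs` (per-repeat metrics),
#'   `metrics` (mean/sd of OA, AA, kappa), `per_class` (mean/sd per-class
#'   accuracy), `seeds`.
#' @export
repeat_experiment <- function(cube, gt, config, tspec, train_frac, val_frac,
                              n_repeats = 5L, seeds = NULL) {
  stopifnot(n_repeats >= 1)
  if (is.null(seeds)) seeds <- tspec$seed + seq_len(n_repeats) - 1L
  stopifnot(length(seeds) == n_repeats)
  k <- config$n_classes
  runs <- data.frame(seed = seeds, oa = NA_real_, aa = NA_real_,
                     kappa = NA_real_)
  percls <- matrix(NA_real_, n_repeats, k)
  for (i in seq_len(n_repeats)) {
    sd_i <- seeds[i]
    split <- stratified_split(gt, train_frac, val_frac, seed = sd_i)
    sets <- .split_to_sets(cube, gt, split, config$s)
    cfg_i <- config
    cfg_i$seed <- as.integer(sd_i)
    model <- build_sgtn(cfg_i)
    ts_i <- tspec
    ts_i$seed <- as.integer(sd_i)
    fit <- train_sgtn(model, sets$train, sets$val, ts_i)
    cm <- evaluate(fit$model, sets$test)
    runs$oa[i] <- overall_accuracy(cm)
    runs$aa[i] <- average_accuracy(cm)
    runs$kappa[i] <- kappa_coefficient(cm)
    rs <- rowSums(cm)
    percls[i, ] <- ifelse(rs > 0, diag(cm) / rs, NA_real_)
  }
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  metrics <- data.frame(
    metric = c("oa", "aa", "kappa"),
    mean = c(mean(runs$oa), mean(runs$aa), mean(runs$kappa)),
    sd = c(sd0(runs$oa), sd0(runs$aa), sd0(runs$kappa)))
  per_class <- data.frame(
    class = seq_len(k),
    mean = colMeans(percls, na.rm = TRUE),
    sd = if (n_repeats > 1L) apply(percls, 2L, stats::sd, na.rm = TRUE)
         else rep(0, k))
  structure(list(runs = runs, metrics = metrics, per_class = per_class,
                 n_repeats = as.integer(n_repeats), seeds = seeds),
            class = "repeat_summary")
}

#' Predict a full-scene classification map
#'
#' Classifies every pixel (labeled and unlabeled) via its mirror-padded
#' patch.
#'
#' @param model A trained `sgtn_model`.
#' @param cube The scene cube; band count must match the model.
#' @param s Patch side (defaults to the model config).
#' @param chunk Pixels per forward batch.
#' @return An integer `rows x cols` matrix of predicted classes.
#' @export
predict_map <- function(model, cube, s = model$config$s, chunk = 256L) {
  stopifnot(inherits(model, "sgtn_model"), inherits(cube, "hsi_cube"))
  if (cube$band_count != model$config$bands)
    stop("cube has ", cube$band_count, " bands; model expects ",
         model$config$bands)
  d <- dim(cube$values)
  s <- as.integer(s)
  s2 <- s * s
  half <- (s - 1L) %/% 2L
  out <- matrix(0L, d[1L], d[2L])
  coords <- cbind(rep(seq_len(d[1L]), times = d[2L]),
                  rep(seq_len(d[2L]), each = d[1L]))
  n <- nrow(coords)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    nb <- length(idx)
    Xb <- matrix(0, nb * s2, cube$band_count)
    for (j in seq_len(nb)) {
      cc <- coords[idx[j], ]
      rows <- .reflect_idx(cc[1L] + (-half):half, d[1L])
      cols <- .reflect_idx(cc[2L] + (-half):half, d[2L])
      w <- cube$values[rows, cols, , drop = FALSE]
      Xb[((j - 1L) * s2 + 1L):(j * s2), ] <-
        matrix(aperm(w, c(2L, 1L, 3L)), s2, cube$band_count)
    }
    logits <- .sgtn_fwd(Xb, nb, model)$logits
    out[coords[idx, , drop = FALSE]] <- max.col(logits, ties.method = "first")
  }
  out
}

#' Deterministic per-class color palette
#'
#' @param k Number of classes.
#' @return Character vector of `k` hex colors (label 0 renders as black).
#' @export
class_palette <- function(k) {
  grDevices::hcl.colors(k, palette = "Dark 3")
}

#' Render a class map to PNG
#'
#' Ground truth and predictions share the same palette; label 0 (or pixels
#' masked via `mask`) render as the black background.
#'
#' @param map Integer matrix of class labels.
#' @param path Output PNG path.
#' @param k Number of classes (defaults to `max(map)`).
#' @param mask Optional logical matrix or a [gt_map()]; where `mask` is
#'   `TRUE` (or the gt label is 0) the pixel renders as background.
#' @return `path`, invisibly.
#' @export
render_map <- function(map, path, k = max(map), mask = NULL) {
  pal <- grDevices::col2rgb(class_palette(k)) / 255
  if (inherits(mask, "gt_map")) mask <- mask$labels == 0L
  img <- array(0, c(nrow(map), ncol(map), 3L))
  for (ch in 1:3) {
    plane <- matrix(0, nrow(map), ncol(map))
    sel <- map > 0L
    if (!is.null(mask)) sel <- sel & !mask
    plane[sel] <- pal[ch, map[sel]]
    img[, , ch] <- plane
  }
  png::writePNG(img, path)
  invisible(path)
}
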