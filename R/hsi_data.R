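# Hyperspectral cube + ground-truth handling: loading, band removal,
# per-band min-max normalization, per-class stratified splitting with the
# floor rule, and mirror-padded patch extraction with center-pixel labels.

#' Hyperspectral cube container
#'
#' @param values Numeric `rows x columns x bands` array (a matrix is treated
#'   as a single band). Must contain no NA/NaN.
#' @param name Free-text name.
#' @param dropped_bands Integer vector of original band indices already
#'   removed from `values`.
#' @param band_map Integer vector mapping current band slots to original band
#'   indices (defaults to the identity).
#' @return A list of class `hsi_cube` with fields `values`, `band_count`,
#'   `dropped_bands`, `band_map`, `name`.
#' @export
hsi_cube <- function(values, name = "", dropped_bands = integer(),
                     band_map = NULL) {
  if (is.matrix(values)) dim(values) <- c(dim(values), 1L)
  if (!is.array(values) || length(dim(values)) != 3L || !is.numeric(values))
    stop("cube values must be a rank-3 numeric array")
  if (any(dim(values) < 1L)) stop("all cube dimensions must be >= 1")
  if (anyNA(values)) stop("cube contains NA/NaN values")
  b <- dim(values)[3L]
  if (is.null(band_map)) band_map <- seq_len(b)
  structure(list(values = values, band_count = b,
                 dropped_bands = as.integer(dropped_bands),
                 band_map = as.integer(band_map), name = name),
            class = "hsi_cube")
}

#' Ground-truth label map container
#'
#' @param labels Integer `rows x columns` matrix; 0 marks unlabeled pixels
#'   and is never a class.
#' @return A list of class `gt_map` with fields `labels` and `class_count`.
#' @export
gt_map <- function(labels) {
  labels <- as.matrix(labels)
  if (!is.numeric(labels)) stop("labels must be numeric")
  if (any(labels < 0)) stop("labels must be non-negative")
  if (any(labels != round(labels))) stop("labels must be integers")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels,
                 class_count = length(unique(labels[labels > 0L]))),
            class = "gt_map")
}

.read_raster_any <- function(path, rank) {
  if (grepl("\\.mat$", path, ignore.case = TRUE)) {
    vars <- read_mat(path)
    hits <- Filter(function(a) length(dim(a)) == rank ||
                     (rank == 2L && is.matrix(a)), vars)
    if (length(hits) == 0L)
      stop("no rank-", rank, " numeric array found in ", path)
    hits[[which.max(vapply(hits, length, numeric(1)))]]
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    read_labels_csv(path)
  } else {
    a <- read_envi(path)
    if (rank == 2L) {
      if (dim(a)[3L] != 1L) stop("label raster must have a single band")
      a <- a[, , 1L]
    }
    a
  }
}

#' Load a hyperspectral cube and its co-registered label map
#'
#' Accepts ENVI rasters, MATLAB v5 containers (the largest rank-3 / rank-2
#' numeric variable is taken), or CSV for the labels.
#'
#' @param path Path to the cube (ENVI data/header or `.mat`).
#' @param gt_path Path to the label map (ENVI, `.mat`, or CSV).
#' @param name Optional dataset name.
#' @return `list(cube = hsi_cube, gt = gt_map)`.
#' @export
load_cube <- function(path, gt_path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!file.exists(gt_path)) stop("file not found: ", gt_path)
  values <- .read_raster_any(path, 3L)
  if (is.matrix(values)) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L)
    stop("cube payload in ", path, " is not rank-3")
  labels <- .read_raster_any(gt_path, 2L)
  labels <- round(labels)
  if (!all(dim(labels) == dim(values)[1:2]))
    stop("label map is ", paste(dim(labels), collapse = "x"),
         " but cube is ", paste(dim(values)[1:2], collapse = "x"))
  list(cube = hsi_cube(values, name = name), gt = gt_map(labels))
}

#' Remove spectral bands (e.g., water-absorption bands)
#'
#' @param cube An [hsi_cube()].
#' @param drop_indices Unique band indices (positions in the current cube) to
#'   remove; remaining bands keep their order.
#' @return The reduced `hsi_cube`; `dropped_bands` records the removed
#'   original band indices.
#' @export
remove_bands <- function(cube, drop_indices) {
  stopifnot(inherits(cube, "hsi_cube"))
  drop_indices <- as.integer(drop_indices)
  if (length(drop_indices) == 0L) return(cube)
  if (anyDuplicated(drop_indices)) stop("drop_indices contains duplicates")
  if (any(drop_indices < 1L | drop_indices > cube$band_count))
    stop("drop index out of range 1..", cube$band_count)
  hsi_cube(cube$values[, , -drop_indices, drop = FALSE], name = cube$name,
           dropped_bands = sort(c(cube$dropped_bands,
                                  cube$band_map[drop_indices])),
           band_map = cube$band_map[-drop_indices])
}

#' Default water-absorption band lists
#'
#' Ships the editable per-dataset drop lists (1-based original band indices)
#' from `inst/extdata/water_bands.yaml`. The benchmark literature states the
#' retained counts (200 for IP, 204 for SA) but not the exact indices, so the
#' lists are configuration, not constants.
#'
#' @param dataset One of `"ip"`, `"sa"`.
#' @param file Optional alternative YAML file with the same schema.
#' @return Integer vector of band indices to drop.
#' @export
default_band_drops <- function(dataset = c("ip", "sa"), file = NULL) {
  dataset <- match.arg(dataset)
  if (is.null(file))
    file <- system.file("extdata", "water_bands.yaml", package = "sgtn",
                        mustWork = TRUE)
  cfg <- yaml::read_yaml(file)
  spec <- cfg[[dataset]]
  if (is.null(spec)) stop("no band list for dataset: ", dataset)
  out <- integer()
  for (part in spec) {
    part <- as.integer(part)
    out <- c(out, if (length(part) == 2L) part[1L]:part[2L] else part)
  }
  sort(unique(out))
}

#' Per-band min-max normalization to [0, 1]
#'
#' Each band is independently rescaled over the whole cube; constant bands
#' map to zero.
#'
#' @param cube An [hsi_cube()].
#' @return The normalized `hsi_cube`.
#' @export
normalize_cube <- function(cube) {
  stopifnot(inherits(cube, "hsi_cube"))
  v <- cube$values
  for (b in seq_len(dim(v)[3L])) {
    rng <- range(v[, , b])
    v[, , b] <- if (rng[2L] > rng[1L])
      (v[, , b] - rng[1L]) / (rng[2L] - rng[1L]) else 0
  }
  hsi_cube(v, name = cube$name, dropped_bands = cube$dropped_bands,
           band_map = cube$band_map)
}

#' Per-class subset sizes under the floor rule
#'
#' `n_train = floor(train_frac * n)`, `n_val = floor(val_frac * (n -
#' n_train))` of the remainder, `n_test` the rest. Counts depend only on the
#' class total and the fractions.
#'
#' @param n Vector of class totals.
#' @param train_frac,val_frac Fractions in (0, 1) with sum < 1.
#' @return A data frame with columns `total`, `train`, `val`, `test`.
#' @export
split_counts <- function(n, train_frac, val_frac) {
  stopifnot(train_frac > 0, val_frac > 0, train_frac + val_frac < 1)
  n <- as.integer(n)
  tr <- as.integer(floor(train_frac * n + 1e-9))
  va <- as.integer(floor(val_frac * (n - tr) + 1e-9))
  data.frame(total = n, train = tr, val = va, test = n - tr - va)
}

#' Stratified per-class train/validation/test split
#'
#' Subset sizes follow [split_counts()]; membership is drawn uniformly at
#' random under `seed`, so counts are seed-independent while membership is
#' seed-dependent. Label 0 is excluded entirely. Coordinates are 1-based
#' `(row, col)`.
#'
#' @param gt A [gt_map()].
#' @param train_frac,val_frac Fractions in (0, 1) with sum < 1.
#' @param seed Integer seed.
#' @return A list of class `dataset_split`: per class, matrices `train`,
#'   `val`, `test` of pixel coordinates, plus `seed` and `fractions`. A class
#'   whose training share floors to zero triggers a warning.
#' @export
stratified_split <- function(gt, train_frac, val_frac, seed = 1L) {
  stopifnot(inherits(gt, "gt_map"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  classes <- sort(unique(gt$labels[gt$labels > 0L]))
  out <- vector("list", length(classes))
  names(out) <- as.character(classes)
  for (i in seq_along(classes)) {
    k <- classes[i]
    coords <- which(gt$labels == k, arr.ind = TRUE)
    dimnames(coords) <- list(NULL, c("row", "col"))
    n <- nrow(coords)
    cc <- split_counts(n, train_frac, val_frac)
    if (cc$train == 0L)
      warning("class ", k, " has n = ", n,
              " samples; training share floors to zero")
    perm <- coords[sample.int(n), , drop = FALSE]
    out[[i]] <- list(
      train = perm[seq_len(cc$train), , drop = FALSE],
      val = perm[seq_len(cc$val) + cc$train, , drop = FALSE],
      test = perm[seq_len(cc$test) + cc$train + cc$val, , drop = FALSE])
  }
  structure(list(classes = out, seed = as.integer(seed),
                 fractions = c(train = train_frac, val = val_frac)),
            class = "dataset_split")
}

#' Tabulate a dataset split
#'
#' @param x A `dataset_split`.
#' @param ... Unused.
#' @return Data frame with per-class `class`, `train`, `val`, `test`, `total`.
#' @export
as.data.frame.dataset_split <- function(x, ...) {
  rows <- lapply(names(x$classes), function(k) {
    cl <- x$classes[[k]]
    data.frame(class = as.integer(k), train = nrow(cl$train),
               val = nrow(cl$val), test = nrow(cl$test),
               total = nrow(cl$train) + nrow(cl$val) + nrow(cl$test))
  })
  do.call(rbind, rows)
}

#' Gather the coordinates of one subset of a split
#'
#' @param split A `dataset_split`.
#' @param subset One of `"train"`, `"val"`, `"test"`.
#' @return Integer matrix of `(row, col)` coordinates over all classes.
#' @export
split_subset <- function(split, subset = c("train", "val", "test")) {
  subset <- match.arg(subset)
  do.call(rbind, lapply(split$classes, `[[`, subset))
}

#' Write a split manifest as CSV
#'
#' Columns: `class`, `row`, `col`, `subset`.
#'
#' @param split A `dataset_split`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_split_csv <- function(split, path) {
  rows <- list()
  for (k in names(split$classes)) {
    cl <- split$classes[[k]]
    for (ss in c("train", "val", "test")) {
      m <- cl[[ss]]
      if (nrow(m) > 0L)
        rows[[length(rows) + 1L]] <-
          data.frame(class = as.integer(k), row = m[, 1L], col = m[, 2L],
                     subset = ss)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

# Reflect 1-based indices into 1..n (mirror padding with the edge included).
.reflect_idx <- function(i, n) {
  if (n == 1L) return(rep.int(1L, length(i)))
  repeat {
    lo <- i < 1L
    hi <- i > n
    if (!any(lo) && !any(hi)) return(i)
    i[lo] <- 1L - i[lo]
    i[hi] <- 2L * n + 1L - i[hi]
  }
}

#' Extract one s x s patch centered on a pixel
#'
#' Borders are filled by mirror reflection of the cube, so every pixel yields
#' a full-size patch.
#'
#' @param cube An [hsi_cube()].
#' @param center Integer `(row, col)`, 1-based.
#' @param s Odd patch side.
#' @param label Optional center-pixel class label to attach.
#' @return A list of class `hsi_patch`: `window` (`s x s x bands`), `center`,
#'   `label`, `s`.
#' @export
extract_patch <- function(cube, center, s, label = NA_integer_) {
  stopifnot(inherits(cube, "hsi_cube"))
  s <- as.integer(s)
  if (s < 1L || s %% 2L == 0L) stop("patch side s must be odd and >= 1")
  d <- dim(cube$values)
  center <- as.integer(center)
  if (center[1L] < 1L || center[1L] > d[1L] ||
      center[2L] < 1L || center[2L] > d[2L])
    stop("center (", center[1L], ",", center[2L], ") outside the image")
  half <- (s - 1L) %/% 2L
  rows <- .reflect_idx(center[1L] + (-half):half, d[1L])
  cols <- .reflect_idx(center[2L] + (-half):half, d[2L])
  structure(list(window = cube$values[rows, cols, , drop = FALSE],
                 center = center, label = label, s = s),
            class = "hsi_patch")
}

#' Build a patch set from labeled pixel coordinates
#'
#' One patch per coordinate, order preserved; each patch's label is the
#' ground truth at its center, which must be nonzero.
#'
#' @param cube An [hsi_cube()].
#' @param gt The paired [gt_map()].
#' @param indices Integer matrix of `(row, col)` coordinates.
#' @param s Odd patch side.
#' @return A list of class `patch_set`: the flattened token matrix `x`
#'   (`n * s^2` rows, one channel per column), `labels`, `centers`, `s`, `n`,
#'   `channels`. Individual patches come from [get_patch()].
#' @export
make_patch_set <- function(cube, gt, indices, s) {
  stopifnot(inherits(cube, "hsi_cube"), inherits(gt, "gt_map"))
  indices <- matrix(as.integer(indices), ncol = 2L)
  s <- as.integer(s)
  if (s < 1L || s %% 2L == 0L) stop("patch side s must be odd and >= 1")
  n <- nrow(indices)
  ch <- cube$band_count
  labels <- gt$labels[indices]
  if (n > 0L && any(labels == 0L))
    stop("unlabeled pixel (label 0) in patch indices")
  s2 <- s * s
  x <- matrix(0, n * s2, ch)
  d <- dim(cube$values)
  half <- (s - 1L) %/% 2L
  for (i in seq_len(n)) {
    rows <- .reflect_idx(indices[i, 1L] + (-half):half, d[1L])
    cols <- .reflect_idx(indices[i, 2L] + (-half):half, d[2L])
    w <- cube$values[rows, cols, , drop = FALSE]
    x[((i - 1L) * s2 + 1L):(i * s2), ] <- matrix(aperm(w, c(2L, 1L, 3L)),
                                                 s2, ch)
  }
  structure(list(x = x, labels = as.integer(labels), centers = indices,
                 s = s, n = n, channels = ch),
            class = "patch_set")
}

#' Retrieve one patch from a patch set
#'
#' @param ps A [make_patch_set()] result.
#' @param i Patch index (order is preserved from the input coordinates).
#' @return An `hsi_patch`.
#' @export
get_patch <- function(ps, i) {
  stopifnot(inherits(ps, "patch_set"), i >= 1L, i <= ps$n)
  s2 <- ps$s * ps$s
  X <- ps$x[((i - 1L) * s2 + 1L):(i * s2), , drop = FALSE]
  structure(list(window = .unflatten_map(X, ps$s),
                 center = ps$centers[i, ], label = ps$labels[i], s = ps$s),
            class = "hsi_patch")
}

#' @export
length.patch_set <- function(x) x$n

#' Reference per-class split tables for the three benchmarks
#'
#' The published per-class train/validation/test sizes for Indian Pines
#' (10%/10%/80%), Salinas, and Pavia University (1%/1%/98%), shipped as
#' CSV under `extdata`. Useful for verifying that [split_counts()]
#' reproduces the benchmark protocol from the class totals alone.
#'
#' @return Named list of data frames (`ip`, `sa`, `pu`) with columns
#'   `class`, `train`, `val`, `test`, `total`.
#' @export
benchmark_split_tables <- function() {
  rd <- function(f)
    utils::read.csv(system.file("extdata", f, package = "sgtn",
                                mustWork = TRUE))
  list(ip = rd("ip_split_table.csv"),
       sa = rd("sa_split_table.csv"),
       pu = rd("pu_split_table.csv"))
}
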