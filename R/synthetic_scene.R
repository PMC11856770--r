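# Synthetic labeled hyperspectral scenes with controllable class
# separability: smooth per-class spectral signatures (sums of Gaussian bumps
# over band index), spatially contiguous class regions (rectangle tiling or
# Voronoi cells), optional spectrally confusable class pairs (one class's
# signature is the other's with bump centers shifted by a small offset),
# additive white Gaussian noise, and an unlabeled background fraction.

#' Specify a synthetic scene
#'
#' @param rows,cols Spatial size.
#' @param bands Number of spectral bands.
#' @param n_classes Number of classes (>= 2).
#' @param region_model `"rectangles"` (contiguous per-class blocks, mimicking
#'   agricultural fields) or `"voronoi"` (nearest-site cells).
#' @param signature_means Optional per-class list of bump lists; each bump is
#'   `list(center =, width =, amplitude =)` over band index. Defaults to one
#'   bump per class with centers spread over the spectral range, width
#'   `bands / 8`, amplitude 1.
#' @param noise_sd Standard deviation of the additive per-band Gaussian
#'   noise (>= 0).
#' @param confusable_pairs List of `list(a =, b =, offset =)`: class `b`
#'   receives class `a`'s signature with every bump center shifted by
#'   `offset` bands, making the pair spectrally confusable for small offsets.
#' @param unlabeled_fraction Fraction of pixels whose label is masked to 0
#'   (the pixels keep their region spectrum, mimicking unannotated
#'   background).
#' @param seed Integer seed; scenes are reproducible bit-for-bit.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(rows, cols, bands, n_classes,
                       region_model = c("rectangles", "voronoi"),
                       signature_means = NULL, noise_sd = 0.05,
                       confusable_pairs = list(), unlabeled_fraction = 0.1,
                       seed = 1L) {
  region_model <- match.arg(region_model)
  stopifnot(rows >= 1, cols >= 1, bands >= 1)
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (unlabeled_fraction < 0 || unlabeled_fraction >= 1)
    stop("unlabeled_fraction must be in [0, 1)")
  for (p in confusable_pairs)
    if (!all(c("a", "b", "offset") %in% names(p)) ||
        p$a < 1 || p$a > n_classes || p$b < 1 || p$b > n_classes)
      stop("confusable_pairs entries need fields a, b (class ids), offset")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 bands = as.integer(bands), n_classes = as.integer(n_classes),
                 region_model = region_model,
                 signature_means = signature_means,
                 noise_sd = noise_sd, confusable_pairs = confusable_pairs,
                 unlabeled_fraction = unlabeled_fraction,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

.default_bumps <- function(class_id, spec) {
  centers <- seq(0.15, 0.85, length.out = spec$n_classes) * spec$bands
  list(list(center = centers[class_id], width = spec$bands / 8,
            amplitude = 1))
}

.class_bumps <- function(class_id, spec) {
  bumps <- if (!is.null(spec$signature_means))
    spec$signature_means[[class_id]] else .default_bumps(class_id, spec)
  for (p in spec$confusable_pairs) {
    if (p$b == class_id) {
      bumps <- if (!is.null(spec$signature_means))
        spec$signature_means[[p$a]] else .default_bumps(p$a, spec)
      bumps <- lapply(bumps, function(bp) {
        bp$center <- bp$center + p$offset
        bp
      })
    }
  }
  bumps
}

#' Spectral signature of a class
#'
#' Deterministic given the spec: a sum of Gaussian bumps over band index,
#' non-negative everywhere.
#'
#' @param class_id Class in `1..n_classes`.
#' @param spec A [scene_spec()].
#' @return Numeric vector of length `bands`.
#' @export
class_signature <- function(class_id, spec) {
  stopifnot(inherits(spec, "scene_spec"))
  if (class_id < 1 || class_id > spec$n_classes)
    stop("unknown class: ", class_id)
  b <- seq_len(spec$bands)
  sig <- numeric(spec$bands)
  for (bp in .class_bumps(class_id, spec))
    sig <- sig + bp$amplitude * exp(-(b - bp$center)^2 / (2 * bp$width^2))
  sig
}

.region_labels <- function(spec) {
  k <- spec$n_classes
  if (spec$region_model == "rectangles") {
    nr <- max(1L, floor(sqrt(k)))
    nc <- ceiling(k / nr)
    ri <- pmin(ceiling(seq_len(spec$rows) / spec$rows * nr), nr)
    ci <- pmin(ceiling(seq_len(spec$cols) / spec$cols * nc), nc)
    tile <- outer(ri, ci, function(a, b) (a - 1L) * nc + b)
    matrix(((tile - 1L) %% k) + 1L, spec$rows, spec$cols)
  } else {
    sites <- cbind(runif(k, 1, spec$rows), runif(k, 1, spec$cols))
    rr <- matrix(seq_len(spec$rows), spec$rows, spec$cols)
    cc <- matrix(seq_len(spec$cols), spec$rows, spec$cols, byrow = TRUE)
    best <- matrix(1L, spec$rows, spec$cols)
    bestd <- (rr - sites[1, 1])^2 + (cc - sites[1, 2])^2
    for (j in seq_len(k)[-1]) {
      dj <- (rr - sites[j, 1])^2 + (cc - sites[j, 2])^2
      upd <- dj < bestd
      best[upd] <- j
      bestd[upd] <- dj[upd]
    }
    best
  }
}

#' Generate a synthetic labeled scene
#'
#' Every pixel's spectrum is its region class signature plus independent
#' `N(0, noise_sd^2)` noise per band; labels follow the regions, with an
#' `unlabeled_fraction` of pixels masked to label 0 (at least one labeled
#' pixel per class is always retained).
#'
#' @param spec A [scene_spec()].
#' @return `list(cube = hsi_cube, gt = gt_map)`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)
  regions <- .region_labels(spec)
  if (length(unique(as.vector(regions))) < spec$n_classes)
    stop("realized scene does not give every class at least one pixel; ",
         "increase the scene size")
  labels <- regions
  npix <- spec$rows * spec$cols
  nmask <- floor(spec$unlabeled_fraction * npix)
  if (nmask > 0L) {
    masked <- sample.int(npix, nmask)
    labels[masked] <- 0L
    for (k in seq_len(spec$n_classes)) {
      if (!any(labels == k)) {
        idx <- which(regions == k)[1L]
        labels[idx] <- k
      }
    }
  }
  sigs <- vapply(seq_len(spec$n_classes), class_signature, spec = spec,
                 numeric(spec$bands))                      # bands x classes
  values <- array(0, c(spec$rows, spec$cols, spec$bands))
  flat <- matrix(t(sigs[, as.vector(regions), drop = FALSE]),
                 npix, spec$bands)
  if (spec$noise_sd > 0)
    flat <- flat + matrix(rnorm(npix * spec$bands, 0, spec$noise_sd),
                          npix, spec$bands)
  values[] <- flat
  list(cube = hsi_cube(values, name = "synthetic"), gt = gt_map(labels))
}

#' Pairwise class separability of a labeled scene
#'
#' Symmetric table of Euclidean distances between per-class mean spectra,
#' zero on the diagonal.
#'
#' @param cube An [hsi_cube()].
#' @param gt The paired [gt_map()].
#' @return A `k x k` numeric matrix with class labels as dimnames.
#' @export
scene_separability <- function(cube, gt) {
  stopifnot(inherits(cube, "hsi_cube"), inherits(gt, "gt_map"))
  classes <- sort(unique(gt$labels[gt$labels > 0L]))
  if (length(classes) < 2L) stop("need at least 2 classes present")
  flat <- matrix(cube$values, prod(dim(cube$values)[1:2]), cube$band_count)
  means <- t(vapply(classes, function(k) {
    idx <- which(gt$labels == k)
    if (length(idx) == 0L) stop("class ", k, " has no pixels")
    colMeans(flat[idx, , drop = FALSE])
  }, numeric(cube$band_count)))
  D <- as.matrix(stats::dist(means))
  dimnames(D) <- list(classes, classes)
  D
}

#' Write / read a synthetic scene on disk
#'
#' The cube goes to an ENVI raster (+ header), the labels to CSV, and the
#' scene spec to YAML.
#'
#' @param scene A [generate_scene()] result.
#' @param dir Output directory (created if needed).
#' @param stem File stem for the three outputs.
#' @param spec Optional [scene_spec()] to record alongside.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_scene <- function(scene, dir, stem = "scene", spec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cube_path <- file.path(dir, paste0(stem, "_cube.dat"))
  labels_path <- file.path(dir, paste0(stem, "_labels.csv"))
  write_envi(scene$cube$values, cube_path)
  write_labels_csv(scene$gt$labels, labels_path)
  paths <- c(cube = cube_path, labels = labels_path)
  if (!is.null(spec)) {
    spec_path <- file.path(dir, paste0(stem, "_spec.yaml"))
    yaml::write_yaml(unclass(spec), spec_path)
    paths <- c(paths, spec = spec_path)
  }
  invisible(paths)
}
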