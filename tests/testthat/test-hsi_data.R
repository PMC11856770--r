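test_that("containers enforce their invariants, including the degenerate minimum", {
  expect_error(hsi_cube(array(c(1, NaN), c(1, 1, 2))), "NA/NaN")
  expect_error(hsi_cube(matrix(letters[1:4], 2)), "numeric")
  expect_error(gt_map(matrix(-1, 2, 2)), "non-negative")
  expect_error(gt_map(matrix(1.5, 2, 2)), "integers")

  cube <- hsi_cube(array(0.3, c(1, 1, 1)))
  gt <- gt_map(matrix(0L, 1, 1))
  expect_equal(cube$band_count, 1L)
  expect_equal(gt$class_count, 0L)
})

test_that("load_cube reads ENVI and MAT pairs and rejects dimension mismatches", {
  dir <- withr::local_tempdir()
  set.seed(1)
  vals <- array(rnorm(10 * 10 * 5), c(10, 10, 5))
  labs <- matrix(sample(0:3, 100, replace = TRUE), 10, 10)

  cube_path <- file.path(dir, "cube.dat")
  lab_path <- file.path(dir, "labs.csv")
  write_envi(vals, cube_path)
  write_labels_csv(labs, lab_path)
  loaded <- load_cube(cube_path, lab_path)
  expect_equal(loaded$cube$values, vals)
  expect_equal(loaded$cube$band_count, 5L)
  expect_equal(loaded$gt$labels, labs, ignore_attr = TRUE)

  mat_path <- file.path(dir, "scene.mat")
  write_mat(list(cube = vals, gt = labs), mat_path)
  via_mat <- load_cube(mat_path, mat_path)
  expect_equal(via_mat$cube$values, vals)
  expect_equal(via_mat$gt$class_count, 3L)

  bad <- matrix(1L, 9, 10)
  bad_path <- file.path(dir, "bad.csv")
  write_labels_csv(bad, bad_path)
  expect_error(load_cube(cube_path, bad_path), "9x10")
  expect_error(load_cube(file.path(dir, "nope.dat"), lab_path), "not found")
})

test_that("remove_bands drops the listed bands and records original indices", {
  mk <- function(b) hsi_cube(array(seq_len(4 * 3 * b), c(4, 3, b)))
  ip <- remove_bands(mk(220), default_band_drops("ip"))
  expect_equal(ip$band_count, 200L)
  sa <- remove_bands(mk(224), default_band_drops("sa"))
  expect_equal(sa$band_count, 204L)

  cube <- mk(6)
  expect_identical(remove_bands(cube, integer()), cube)
  expect_error(remove_bands(cube, c(2, 2)), "duplicates")
  expect_error(remove_bands(cube, 7), "out of range")

  # two-step removal keeps tracking original band indices
  step1 <- remove_bands(cube, c(2L, 5L))
  step2 <- remove_bands(step1, 1L)   # original band 1
  expect_equal(step2$dropped_bands, c(1L, 2L, 5L))
  expect_equal(step2$band_map, c(3L, 4L, 6L))
  expect_equal(step2$values[1, 1, ], cube$values[1, 1, c(3, 4, 6)])
})

test_that("normalize_cube rescales each band to [0,1] with constant bands at 0", {
  v <- array(0, c(2, 2, 3))
  v[, , 1] <- matrix(c(100, 300, 200, 150), 2)
  v[, , 2] <- 7                           # constant band
  set.seed(4)
  v[, , 3] <- rnorm(4)
  nc <- normalize_cube(hsi_cube(v))
  expect_equal(nc$values[1, 2, 1], 0.5)   # value 200 between 100 and 300
  expect_true(all(nc$values[, , 2] == 0))
  # per-band extrema verified by direct scan
  set.seed(5)
  r <- normalize_cube(hsi_cube(array(rnorm(4 * 4 * 3), c(4, 4, 3))))
  for (b in 1:3) {
    expect_equal(min(r$values[, , b]), 0)
    expect_equal(max(r$values[, , b]), 1)
  }
})

test_that("split counts follow the per-class floor rule", {
  expect_equal(unlist(split_counts(46, 0.10, 0.10)[, c("train", "val", "test")]),
               c(train = 4, val = 4, test = 38))
  expect_equal(unlist(split_counts(11271, 0.01, 0.01)[, c("train", "val", "test")]),
               c(train = 112, val = 111, test = 11048))
  expect_equal(unlist(split_counts(18649, 0.01, 0.01)[, c("train", "val", "test")]),
               c(train = 186, val = 184, test = 18279))
  # by hand: floor(0.1*10) = 1, floor(0.1*(10-1)) = 0, rest 9
  expect_equal(unlist(split_counts(10, 0.10, 0.10)[, c("train", "val", "test")]),
               c(train = 1, val = 0, test = 9))
})

test_that("stratified_split partitions classes; counts are seed-free, membership is not", {
  labs <- matrix(0L, 12, 12)
  labs[1:6, ] <- 1L
  labs[7:10, ] <- 2L
  labs[11:12, 1:10] <- 3L
  gt <- gt_map(labs)
  sp1 <- stratified_split(gt, 0.2, 0.2, seed = 1)
  sp2 <- stratified_split(gt, 0.2, 0.2, seed = 2)

  for (k in names(sp1$classes)) {
    cl <- sp1$classes[[k]]
    all_coords <- rbind(cl$train, cl$val, cl$test)
    expect_equal(nrow(all_coords), sum(labs == as.integer(k)))
    expect_false(any(duplicated(all_coords)))
    got <- which(labs == as.integer(k), arr.ind = TRUE)
    expect_setequal(paste(all_coords[, 1], all_coords[, 2]),
                    paste(got[, 1], got[, 2]))
  }
  # counts identical across seeds, train membership different
  expect_equal(as.data.frame(sp1), as.data.frame(sp2))
  expect_false(identical(sp1$classes[["1"]]$train[order(sp1$classes[["1"]]$train[, 1],
                                                        sp1$classes[["1"]]$train[, 2]), ],
                         sp2$classes[["1"]]$train[order(sp2$classes[["1"]]$train[, 1],
                                                        sp2$classes[["1"]]$train[, 2]), ]))
  # a class whose training share floors to zero warns but still splits
  tiny <- gt_map(matrix(c(rep(1L, 5), rep(2L, 45)), 5, 10))
  expect_warning(stratified_split(tiny, 0.1, 0.1, seed = 1), "floors to zero")
})

test_that("extract_patch mirrors borders and matches the pad-then-crop oracle", {
  set.seed(7)
  vals <- array(rnorm(20 * 18 * 2), c(20, 18, 2))
  cube <- hsi_cube(vals)

  # interior: the window is the literal neighborhood
  p <- extract_patch(cube, c(10, 9), 13)
  expect_equal(p$window, vals[4:16, 3:15, , drop = FALSE])

  # borders: corners and random centers vs the oracle
  for (s in c(3L, 5L)) {
    centers <- rbind(c(1, 1), c(1, 18), c(20, 1), c(20, 18),
                     cbind(sample(20, 4), sample(18, 4)))
    for (i in seq_len(nrow(centers))) {
      got <- extract_patch(cube, centers[i, ], s)$window
      expect_equal(got, pad_crop_patch(vals, centers[i, ], s))
    }
  }

  # s = 1 is the pixel's own spectrum
  expect_equal(drop(extract_patch(cube, c(5, 5), 1)$window), vals[5, 5, ])
  expect_error(extract_patch(cube, c(5, 5), 4), "odd")
  expect_error(extract_patch(cube, c(0, 5), 3), "outside")
})

test_that("make_patch_set preserves order, labels from center pixels, and rejects label 0", {
  scene <- tiny_scene()
  idx <- which(scene$gt$labels > 0, arr.ind = TRUE)[c(3, 11, 27), ]
  ps <- make_patch_set(scene$cube, scene$gt, idx, 5)
  expect_s3_class(ps, "patch_set")
  expect_equal(length(ps), 3L)
  expect_equal(ps$labels, scene$gt$labels[idx])
  for (i in 1:3) {
    p <- get_patch(ps, i)
    expect_equal(p$window,
                 extract_patch(scene$cube, idx[i, ], 5)$window)
    expect_equal(p$label, scene$gt$labels[idx[i, 1], idx[i, 2]])
  }
  empty <- make_patch_set(scene$cube, scene$gt,
                          matrix(integer(), ncol = 2), 5)
  expect_equal(length(empty), 0L)
  bad <- which(scene$gt$labels == 0, arr.ind = TRUE)[1, , drop = FALSE]
  expect_error(make_patch_set(scene$cube, scene$gt, bad, 5), "unlabeled")
})
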