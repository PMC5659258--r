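make_two_class_phantom <- function(dims = c(40, 40, 40), seed = 5) {
  set.seed(seed)
  vol <- array(0.35 + rnorm(prod(dims), 0, 0.03), dims)
  mask <- array(FALSE, dims)
  centers <- rbind(c(10, 12, 12), c(28, 28, 14), c(14, 28, 30), c(30, 10, 30))
  for (i in seq_len(nrow(centers))) {
    b <- ball_volume(dims, centers[i, ], 13) > 0
    vol[b] <- vol[b] + 0.25
    mask <- mask | b
  }
  list(vol = image_volume(vol), mask = mask, centers = centers)
}

sample_mask_annotations <- function(mask, n, seed = 1) {
  set.seed(seed)
  d <- dim(mask)
  pick <- function(idx, cls) {
    idx <- sample(idx, min(n, length(idx)))
    i0 <- idx - 1L
    data.frame(z = i0 %% d[1], y = (i0 %/% d[1]) %% d[2],
               x = i0 %/% (d[1] * d[2]), class = cls)
  }
  rbind(pick(which(mask), "cell"), pick(which(!mask), "background"))
}

test_that("features vanish on constant volumes and respond to an impulse", {
  const <- image_volume(array(0.5, c(16, 16, 16)))
  fs <- compute_features(const, scales_um = c(0.65, 1.3))
  gm <- fs$data[, grep("gradmag", fs$feature_names)]
  dg <- fs$data[, grep("dog", fs$feature_names)]
  expect_equal(max(abs(gm)), 0, tolerance = 1e-12)
  expect_equal(max(abs(dg)), 0, tolerance = 1e-12)

  # single bright voxel: the DoG response is the kernel itself --
  # positive at the impulse, negative in a shell around it
  imp <- array(0, c(17, 17, 17))
  imp[9, 9, 9] <- 1
  fs2 <- compute_features(image_volume(imp), scales_um = 1.3)
  dog <- fs2$data[, grep("^dog", fs2$feature_names)]
  dim(dog) <- c(17, 17, 17)
  expect_gt(dog[9, 9, 9], 0)
  # sigma = 2 voxels: past the zero crossing (~2.2 sigma) the wider
  # Gaussian dominates and the response turns negative
  expect_lt(dog[9, 9, 14], 0)
})

test_that("structure tensor of a plane has one dominant eigenvalue", {
  arr <- array(0, c(24, 24, 24))
  arr[, , 12:24] <- 1   # plane normal to x
  fs <- compute_features(image_volume(arr), scales_um = 1.3)
  get <- function(nm) {
    v <- fs$data[, nm]
    dim(v) <- c(24, 24, 24)
    v
  }
  e1 <- get("st_ev1_s1.3"); e2 <- get("st_ev2_s1.3"); e3 <- get("st_ev3_s1.3")
  # at the face, one strong eigenvalue, two near zero
  expect_gt(e1[12, 12, 12], 10 * max(abs(e2[12, 12, 12]), abs(e3[12, 12, 12])))
  # eigenvalues sorted descending everywhere
  expect_true(all(fs$data[, "st_ev1_s1.3"] >= fs$data[, "st_ev2_s1.3"] - 1e-12))
  expect_true(all(fs$data[, "st_ev2_s1.3"] >= fs$data[, "st_ev3_s1.3"] - 1e-12))
})

test_that("feature computation is translation-equivariant", {
  base <- array(0, c(24, 24, 24))
  base[8:12, 8:12, 8:12] <- 1
  shift <- array(0, c(24, 24, 24))
  shift[11:15, 11:15, 11:15] <- 1
  f1 <- compute_features(image_volume(base), scales_um = 0.65)
  f2 <- compute_features(image_volume(shift), scales_um = 0.65)
  a1 <- f1$data[, "dog_s0.65"]; dim(a1) <- c(24, 24, 24)
  a2 <- f2$data[, "dog_s0.65"]; dim(a2) <- c(24, 24, 24)
  # compare away from boundaries (reflection breaks equivariance at edges)
  expect_equal(a1[7:14, 7:14, 7:14], a2[10:17, 10:17, 10:17],
               tolerance = 1e-10)
})

test_that("classifier separates a clean two-class phantom and is reproducible", {
  tc <- make_two_class_phantom()
  fs <- compute_features(tc$vol, scales_um = c(1.3, 2.6))
  ann <- sample_mask_annotations(tc$mask, 400)
  clf <- train_classifier(fs, ann, n_trees = 50, seed = 7)

  # training-voxel accuracy on a separable problem
  lin <- 1L + ann$z + dim(tc$mask)[1] * (ann$y + dim(tc$mask)[2] * ann$x)
  pm <- predict_probabilities(clf, fs)
  pred_cell <- pm$cell[lin] > 0.5
  expect_equal(mean(pred_cell == (ann$class == "cell")), 1.0)

  # determinism: same seed, same predictions
  clf2 <- train_classifier(fs, ann, n_trees = 50, seed = 7)
  pm2 <- predict_probabilities(clf2, fs)
  expect_equal(pm$cell, pm2$cell)

  # probabilities sum to one at every voxel
  tot <- pm$cell + pm$background
  expect_lt(max(abs(tot - 1)), 1e-6)

  # mean P_cell inside cells exceeds outside
  expect_gt(mean(pm$cell[tc$mask]), mean(pm$cell[!tc$mask]))

  # voxel-level f1 for the cell class on this phantom
  pe <- pixel_eval(array(pm$cell > 0.5, dim(tc$mask)), tc$mask)
  expect_gte(pe$f[["f1"]], 0.7)
})

test_that("training rejects single-class labels and manifest mismatches", {
  tc <- make_two_class_phantom(dims = c(20, 20, 20))
  fs <- compute_features(tc$vol, scales_um = 1.3)
  ann <- sample_mask_annotations(tc$mask, 50)
  one <- ann[ann$class == "cell", ]
  expect_error(train_classifier(fs, one, n_trees = 10, seed = 1),
               "at least 2 classes")
  expect_error(train_classifier(fs, ann, n_trees = 10), "seed")

  clf <- train_classifier(fs, ann, n_trees = 10, seed = 1)
  other <- suppressWarnings(compute_features(tc$vol, scales_um = 2.6))
  expect_error(predict_probabilities(clf, other), "manifest mismatch")
})

test_that("classifier model files round-trip with their manifest", {
  dir <- withr::local_tempdir()
  tc <- make_two_class_phantom(dims = c(20, 20, 20))
  fs <- compute_features(tc$vol, scales_um = 1.3)
  ann <- sample_mask_annotations(tc$mask, 50)
  clf <- train_classifier(fs, ann, n_trees = 10, seed = 1)
  f <- file.path(dir, "model.rds")
  save_classifier(clf, f)
  clf2 <- load_classifier(f)
  expect_equal(predict_probabilities(clf2, fs)$cell,
               predict_probabilities(clf, fs)$cell)
})

test_that("padded-block prediction matches in-place prediction off the edges", {
  tc <- make_two_class_phantom(dims = c(40, 40, 40))
  fs <- compute_features(tc$vol, scales_um = 1.3)
  ann <- sample_mask_annotations(tc$mask, 300)
  clf <- train_classifier(fs, ann, n_trees = 30, seed = 2)
  pm_full <- predict_probabilities(clf, fs)

  blk <- extract_block(tc$vol, c(8, 8, 8), c(24, 24, 24), pad = 8)
  pm_blk <- predict_probabilities(clf, image_volume(blk$data))
  # compare the block's core interior, > kernel support from block edges
  core_in_block <- pm_blk$cell[9:32, 9:32, 9:32]   # the core region
  full_core <- pm_full$cell[9:32, 9:32, 9:32]
  inner <- 9:16   # keep a generous margin from the padded block's faces
  expect_equal(core_in_block[inner, inner, inner],
               full_core[inner, inner, inner], tolerance = 1e-8)
})
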