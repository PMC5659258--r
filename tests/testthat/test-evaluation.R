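test_that("fbeta follows the weighted harmonic-mean formula", {
  # identity: p = r = x gives f_beta = x for any beta
  for (b in c(0.5, 1, 2))
    expect_equal(fbeta(0.73, 0.73, b), 0.73)
  expect_equal(fbeta(0.86, 0.84, 1), 0.8499, tolerance = 5e-5)
  expect_equal(fbeta(1, 0, 2), 0)
  expect_equal(fbeta(0, 0, 1), 0)
  # symmetric in (p, r) only for beta = 1; monotone in each argument
  expect_equal(fbeta(0.9, 0.5, 1), fbeta(0.5, 0.9, 1))
  expect_false(isTRUE(all.equal(fbeta(0.9, 0.5, 2), fbeta(0.5, 0.9, 2))))
  expect_gt(fbeta(0.8, 0.6, 2), fbeta(0.7, 0.6, 2))
  expect_gt(fbeta(0.8, 0.7, 2), fbeta(0.8, 0.6, 2))
})

test_that("pixel evaluation counts voxels and conserves masks", {
  a <- ball_volume(c(20, 20, 20), c(10, 10, 10), 9)
  expect_equal(pixel_eval(a, a)$p, 1)
  expect_equal(pixel_eval(a, a)$r, 1)

  b <- ball_volume(c(20, 20, 20), c(4, 4, 4), 3)
  pe <- pixel_eval(a, b)
  expect_equal(pe$p, 0)
  expect_equal(pe$r, 0)

  # prediction = truth dilated by 1: recall 1, precision = |truth|/|pred|
  dil <- binary_dilate_ball(a > 0, 1) * 1
  pe2 <- pixel_eval(dil, a)
  expect_equal(pe2$r, 1)
  expect_equal(pe2$p, sum(a) / sum(dil))
  expect_lt(pe2$p, 1)

  # conservation: tp + fn = |truth|, tp + fp = |pred|
  expect_equal(pe2$tp + pe2$fn, sum(a > 0))
  expect_equal(pe2$tp + pe2$fp, sum(dil > 0))
  expect_error(pixel_eval(a, array(0, c(5, 5, 5))), "shape")
})

test_that("centroid matching is globally-closest-first and order invariant", {
  set.seed(15)
  truth <- matrix(runif(97 * 3, 10, 90), 97, 3)
  detected <- truth[1:96, ] + matrix(runif(96 * 3, -2, 2), 96, 3)
  mr <- match_centroids(detected, truth, max_dist_um = 10)
  expect_equal(mr$p, 1)
  expect_equal(mr$r, 96 / 97)
  expect_equal(length(mr$unmatched_truth), 1L)

  # exact agreement
  mr2 <- match_centroids(truth, truth)
  expect_equal(mr2$p, 1)
  expect_equal(mr2$r, 1)
  expect_true(all(mr2$pairs$dist_um == 0))

  # a global 15 um offset defeats a 10 um radius (well-separated lattice,
  # so no accidental cross pairs either)
  lattice <- as.matrix(expand.grid(x = c(10, 40, 70), y = c(10, 40, 70),
                                   z = c(10, 40, 70)))
  mr3 <- match_centroids(lattice + 15 / sqrt(3), lattice)
  expect_equal(nrow(mr3$pairs), 0L)

  # permutation invariance
  perm <- sample(96)
  mr4 <- match_centroids(detected[perm, ], truth[sample(97), ])
  expect_equal(nrow(mr4$pairs), nrow(mr$pairs))
  expect_equal(sort(mr4$pairs$dist_um), sort(mr$pairs$dist_um))
  expect_lte(nrow(mr$pairs), min(mr$n_detected, mr$n_truth))
})

test_that("each centroid is used at most once, closest pairs win", {
  # two detections near one truth point: only the closer one matches
  truth <- rbind(c(0, 0, 0), c(50, 0, 0))
  detected <- rbind(c(3, 0, 0), c(1, 0, 0))
  mr <- match_centroids(detected, truth, max_dist_um = 10)
  expect_equal(nrow(mr$pairs), 1L)
  expect_equal(mr$pairs$detected, 2L)
  expect_equal(mr$pairs$dist_um, 1)
})

test_that("edge margins drop boundary centroids from both sets", {
  truth <- rbind(c(1, 50, 50), c(50, 50, 50))
  detected <- rbind(c(1.5, 50, 50), c(50.2, 50, 50))
  bounds <- list(lo = c(0, 0, 0), hi = c(100, 100, 100))
  mr <- match_centroids(detected, truth, bounds = bounds, edge_margin_um = 5)
  expect_equal(mr$n_detected, 1L)
  expect_equal(mr$n_truth, 1L)
  expect_equal(mr$excluded_detected, 1L)
  expect_equal(mr$excluded_truth, 1L)
  expect_equal(mr$p, 1)
})

test_that("SNR in dB follows 20 log10(s/n) on labeled markers", {
  vol <- array(1, c(10, 10, 10))
  interior <- array(0L, c(10, 10, 10))
  exterior <- array(0L, c(10, 10, 10))
  interior[2, 2, 2] <- 1L; exterior[8, 8, 8] <- 1L
  vol[2, 2, 2] <- 10
  out <- compute_snr(vol, interior, exterior)
  expect_equal(out$samples$snr_db, 20)

  vol[2, 2, 2] <- 1
  expect_equal(compute_snr(vol, interior, exterior)$samples$snr_db, 0)

  vol[2, 2, 2] <- -1
  expect_error(compute_snr(vol, interior, exterior), "positive")
  expect_error(compute_snr(vol, interior, array(0L, c(10, 10, 10))),
               "shared")
})

test_that("grid search scores every point and recovers the true size", {
  dims <- c(40, 40, 40)
  truth_mask <- ball_volume(dims, c(12, 12, 12), 12) +
    ball_volume(dims, c(28, 28, 28), 12)
  p <- gauss_blur3(truth_mask, 1)
  p <- pmin(pmax(p, 0), 1); dim(p) <- dims
  truth_cells <- vox_to_um(rbind(c(12, 12, 12), c(28, 28, 28)),
                           0.65)[, c(3, 2, 1)]

  single <- data.frame(cell_size_vox = 12, stop_threshold = 0.4)
  gs1 <- grid_search(single, p, truth_cells, objective = "f1_cells")
  expect_equal(nrow(gs1$table), 1L)
  expect_equal(gs1$best_score, 1)

  grid <- expand.grid(cell_size_vox = c(6, 12, 18),
                      stop_threshold = c(0.4, 0.6))
  gs <- grid_search(grid, p, truth_cells, objective = "f1_cells")
  expect_equal(gs$best$cell_size_vox, 12)
  # table reproduces individual runs
  i <- which(gs$table$cell_size_vox == 18 & gs$table$stop_threshold == 0.4)
  det <- detect_cells(p, detection_params(cell_size_vox = 18,
                                          stop_threshold = 0.4))
  mr <- match_centroids(det, truth_cells)
  expect_equal(gs$table$score[i], fbeta(mr$p, mr$r, 1))

  # degenerate: thresholds too high, all scores 0, warn and return first
  dead <- expand.grid(cell_size_vox = c(6, 12),
                      stop_threshold = 0.99)
  expect_warning(gs0 <- grid_search(dead, p * 0.2, truth_cells,
                                    objective = "f1_cells"), "scored 0")
  expect_equal(gs0$best_score, 0)
})

test_that("grid search tunes vessels by f2", {
  dims <- c(30, 30, 30)
  mask <- array(0, dims); mask[, 14:16, 14:16] <- 1
  p <- gauss_blur3(mask, 1); dim(p) <- dims
  grid <- expand.grid(threshold = c(0.2, 0.5, 0.8),
                      dilation_radius_vox = 0, min_component_vox = 1)
  gs <- grid_search(grid, p, mask, objective = "f2_vessels")
  expect_equal(nrow(gs$table), 3L)
  i_best <- which.max(gs$table$score)
  pe <- pixel_eval(segment_vessels(p, gs$table$threshold[i_best], 0, 1), mask,
                   betas = 2)
  expect_equal(gs$best_score, pe$f[["f2"]])
})

test_that("Rose-criterion conversion and crossing recovery", {
  expect_equal(half_period_resolution(0.383), 1.31, tolerance = 0.005)
  expect_equal(half_period_resolution(0.525), 0.95, tolerance = 0.005)
  expect_equal(half_period_resolution(0.5), 1.0)
  expect_error(half_period_resolution(0), "positive")
})

test_that("resolution estimation recovers a designed spectral crossing", {
  set.seed(16)
  n <- 64
  vs <- 1.0
  sigma <- 2.0
  # signal: white noise low-passed by a Gaussian, whose log power
  # spectrum is close to quadratic in f over the fitted band
  w <- array(rnorm(n^3), c(n, n, n))
  sig <- gauss_blur3(w, sigma)
  # design the crossing on the *measured* radial signal spectrum: pick
  # the flat noise power N0 so that SPS(f_c) = 5 * N0 exactly at f_c
  f_c <- 0.18
  planes <- lapply(seq_len(n), function(i) array(sig[i, , ], c(n, n)))
  sps <- tomocell:::radial_power_spectrum(planes, vs)
  s_at_fc <- exp(stats::approx(sps$freq, log(sps$power), xout = f_c)$y)
  n0 <- s_at_fc / 5
  noise <- array(rnorm(n^3, 0, sqrt(n0)), c(n, n, n))
  res <- estimate_resolution(image_volume(sig, vs),
                             image_volume(noise, vs),
                             n_planes = 64, band = c(0.05, 0.28))
  for (orient in c("xy", "xz")) {
    expect_lt(abs(res[[orient]]$f_cross - f_c) / f_c, 0.1)
    expect_lt(abs(res[[orient]]$resolution_um - 1 / (2 * f_c)) /
                (1 / (2 * f_c)), 0.1)
  }
})
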