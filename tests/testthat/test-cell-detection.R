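test_that("spherical templates have the exact ball support, unit sum", {
  t1 <- make_template(1)
  expect_equal(nrow(t1$offsets), 1L)
  expect_equal(t1$weight, 1)

  # diameter 3: center + 6 face + 12 edge neighbours; corners (sqrt(3) > 1.5)
  # are excluded
  t3 <- make_template(3)
  expect_equal(nrow(t3$offsets), 19L)
  expect_equal(nrow(t3$offsets) * t3$weight, 1)

  for (d in c(2, 5, 9, 18)) {
    tm <- make_template(d)
    r2 <- rowSums(tm$offsets^2)
    expect_true(all(r2 <= (d / 2)^2 + 1e-9))
    expect_equal(nrow(tm$offsets) * tm$weight, 1)
  }
  expect_error(make_template(0), ">= 1")
})

test_that("FFT correlation equals the direct-space weighted mean", {
  set.seed(11)
  p <- array(runif(20^3), c(20, 20, 20))
  cc <- correlate(p, make_template(5))
  expect_equal(cc, oracle_correlate(p, 5), tolerance = 1e-9)

  ones <- array(1, c(16, 16, 16))
  cc1 <- correlate(ones, make_template(5))
  interior <- cc1[4:13, 4:13, 4:13]
  expect_equal(max(abs(interior - 1)), 0, tolerance = 1e-9)

  expect_equal(max(abs(correlate(array(0, c(12, 12, 12)),
                                 make_template(5)))), 0)
  expect_error(correlate(array(0, c(4, 4, 4)), make_template(9)), "larger")
})

test_that("greedy detection finds isolated cells at their centers", {
  dims <- c(48, 48, 48)
  p <- ball_volume(dims, c(24, 24, 24), 9)
  det <- detect_cells(p, detection_params(cell_size_vox = 9,
                                          stop_threshold = 0.47))
  expect_equal(nrow(det), 1L)
  expect_equal(c(det$z_vox, det$y_vox, det$x_vox), c(24, 24, 24))
  expect_equal(det$score, 1, tolerance = 1e-9)
  expect_false(det$edge)

  expect_equal(nrow(detect_cells(array(0, dims),
                                 detection_params(cell_size_vox = 9))), 0L)

  two <- ball_volume(dims, c(10, 10, 10), 9) +
    ball_volume(dims, c(10, 10, 40), 9)
  det2 <- detect_cells(two, detection_params(cell_size_vox = 9,
                                             stop_threshold = 0.47))
  expect_equal(nrow(det2), 2L)
  # equal scores: order resolved lexicographically by (z, y, x)
  expect_equal(det2$x_vox, c(10, 40))
  expect_equal(det2$y_vox, c(10, 10))
})

test_that("detection equals the full-recompute brute-force oracle", {
  for (seed in 1:6) {
    dims <- c(24, 24, 24) + (seed %% 3) * 4
    p <- random_prob_map(dims, sigma = 2, seed = seed)
    det <- detect_cells(p, detection_params(cell_size_vox = 5,
                                            stop_threshold = 0.6,
                                            max_iterations = 10))
    orc <- oracle_detect(p, 5, 0.6, max_iter = 10)
    if (is.null(orc)) {
      expect_equal(nrow(det), 0L)
    } else {
      expect_equal(nrow(det), nrow(orc))
      expect_equal(det$z_vox, orc$z)
      expect_equal(det$y_vox, orc$y)
      expect_equal(det$x_vox, orc$x)
      expect_equal(det$score, orc$score, tolerance = 1e-9)
    }
  }
})

test_that("detection scores are non-increasing and respect zero-out balls", {
  p <- random_prob_map(c(32, 32, 32), sigma = 1.5, seed = 99)
  det <- detect_cells(p, detection_params(cell_size_vox = 7,
                                          stop_threshold = 0.5,
                                          max_iterations = 30))
  expect_true(nrow(det) >= 2)
  expect_true(all(diff(det$score) <= 1e-12))
  # no centroid inside an earlier detection's zero-out ball
  vox <- as.matrix(det[, c("z_vox", "y_vox", "x_vox")])
  for (i in 2:nrow(det)) {
    dd <- sqrt(colSums((t(vox[seq_len(i - 1), , drop = FALSE]) - vox[i, ])^2))
    expect_true(all(dd > 7 / 2))
  }
})

test_that("edge flags mark detections within a template radius of a face", {
  dims <- c(32, 32, 32)
  p <- ball_volume(dims, c(2, 16, 16), 9)   # clipped at the low-z face
  det <- detect_cells(p, detection_params(cell_size_vox = 9,
                                          stop_threshold = 0.3))
  expect_equal(det$z_vox[1], 2)
  expect_true(det$edge[1])
})

test_that("template-growth curve recovers cell diameter", {
  dims <- c(40, 40, 40)
  p <- ball_volume(dims, c(20, 20, 20), 12)
  est <- estimate_cell_size(p, c(20, 20, 20), d_min = 4, d_max = 24,
                            voxel_size_um = 0.65)
  expect_true(abs(est$diameter_vox - 12) <= 1)
  expect_equal(est$diameter_um, est$diameter_vox * 0.65)
  expect_false(est$degenerate)

  # flat correlation (map identically 1) -> degenerate, returns d_min
  flat <- estimate_cell_size(array(1, dims), c(20, 20, 20), 4, 24)
  expect_true(flat$degenerate)
  expect_equal(flat$diameter_vox, 4)

  # bright nucleus inside a dimmer soma: the estimate tracks the outer ball
  nested <- 0.6 * ball_volume(dims, c(20, 20, 20), 14) +
    0.4 * ball_volume(dims, c(20, 20, 20), 6)
  est2 <- estimate_cell_size(nested, c(20, 20, 20), 4, 24)
  expect_true(abs(est2$diameter_vox - 14) <= 1)

  # window near the boundary: truncated and flagged
  edge <- estimate_cell_size(ball_volume(dims, c(2, 20, 20), 8),
                             c(2, 20, 20), 4, 12)
  expect_true(edge$truncated)
})

test_that("estimate_cell_sizes fills the diameter column of a table", {
  dims <- c(40, 40, 40)
  p <- ball_volume(dims, c(12, 20, 20), 9) +
    ball_volume(dims, c(30, 20, 20), 13)
  det <- detect_cells(p, detection_params(cell_size_vox = 13,
                                          stop_threshold = 0.2))
  det <- estimate_cell_sizes(p, det, d_min = 4, d_max = 20)
  expect_equal(nrow(det), 2L)
  expect_true(all(!is.na(det$diameter_um)))
  got <- sort(round(det$diameter_um / 0.65))
  expect_true(all(abs(got - c(9, 13)) <= 1))
})

test_that("detection parameter validation", {
  expect_error(detection_params(stop_threshold = 0), "stop_threshold")
  expect_error(detection_params(cell_size_vox = 0), "cell_size_vox")
  expect_error(detect_cells(array(2, c(8, 8, 8)),
                            detection_params(cell_size_vox = 3)), "\\[0, 1\\]")
})
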