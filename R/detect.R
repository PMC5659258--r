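#' Spherical detection template
#'
#' A binary ball of the given diameter (in voxels), normalized to unit
#' sum. A voxel offset belongs to the support iff its Euclidean distance
#' from the center is at most `diameter / 2`, so correlating the template
#' with a probability map yields the mean probability over the ball.
#'
#' @param diameter_vox Template diameter in voxels (>= 1).
#' @return A `spherical_template`: list with `diameter_vox`, `offsets`
#'   (n x 3 integer matrix, `(z, y, x)`), `weight` (the common weight,
#'   `1 / n`).
#' @export
make_template <- function(diameter_vox) {
  if (diameter_vox < 1) stop("`diameter_vox` must be >= 1")
  off <- ball_offsets(diameter_vox / 2)
  structure(list(diameter_vox = diameter_vox, offsets = off,
                 weight = 1 / nrow(off)),
            class = "spherical_template")
}

#' Detection parameters
#'
#' Defaults follow the operating point tuned on densely annotated mouse
#' neocortex: template diameter 18 voxels (11.7 um at 0.65 um voxels) and
#' stopping threshold 0.47 on the raw template correlation (a mean
#' probability, so in `[0, 1]`).
#'
#' @param cell_size_vox Template diameter in voxels.
#' @param stop_threshold Stop when the best remaining correlation falls
#'   below this value; in `(0, 1)`.
#' @param max_iterations Hard cap on the number of detections.
#' @param zero_out_diameter_vox Diameter of the ball zeroed around each
#'   accepted detection (default: the template diameter).
#' @param pre_threshold Optional probability cutoff applied to the map
#'   before correlation (voxels below it are zeroed); `NULL` to disable.
#' @return A `detection_params` list.
#' @export
detection_params <- function(cell_size_vox = 18L, stop_threshold = 0.47,
                             max_iterations = 10000L,
                             zero_out_diameter_vox = cell_size_vox,
                             pre_threshold = NULL) {
  if (cell_size_vox < 1) stop("`cell_size_vox` must be >= 1")
  if (stop_threshold <= 0 || stop_threshold >= 1)
    stop("`stop_threshold` must be in (0, 1)")
  if (max_iterations < 1) stop("`max_iterations` must be >= 1")
  structure(list(cell_size_vox = cell_size_vox,
                 stop_threshold = stop_threshold,
                 max_iterations = as.integer(max_iterations),
                 zero_out_diameter_vox = zero_out_diameter_vox,
                 pre_threshold = pre_threshold),
            class = "detection_params")
}

#' Correlate a probability map with a spherical template
#'
#' Computes, at every voxel, the template-weighted mean of the map over
#' the ball centered there (zero-padded outside the volume), via a 3D
#' FFT. Values lie in `[0, 1]` for a probability map.
#'
#' @param p 3D array (probability map) or [image_volume()].
#' @param tmpl A [make_template()] object.
#' @return 3D array of correlation values, same shape as `p`.
#' @export
correlate <- function(p, tmpl) {
  arr <- as_vol_array(p)
  d <- dim(arr)
  R <- max(abs(tmpl$offsets))
  if (any(2 * R + 1 > d)) stop("template larger than volume")
  pd <- vapply(d + 2L * R, function(n) stats::nextn(n, c(2, 3, 5)), 0)
  P <- array(0, pd)
  P[(R + 1):(R + d[1]), (R + 1):(R + d[2]), (R + 1):(R + d[3])] <- arr
  K <- array(0, pd)
  idx <- sweep(tmpl$offsets, 2, pd, function(o, n) (o %% n) + 1L)
  K[cbind(idx[, 1], idx[, 2], idx[, 3])] <- tmpl$weight
  cc <- Re(stats::fft(Conj(stats::fft(K)) * stats::fft(P), inverse = TRUE)) /
    prod(pd)
  out <- cc[(R + 1):(R + d[1]), (R + 1):(R + d[2]), (R + 1):(R + d[3]),
            drop = FALSE]
  dim(out) <- d
  pmin(pmax(out, 0), 1)
}

#' Greedy matching-pursuit cell detection
#'
#' Iteratively (1) correlates the cell probability map with a spherical
#' template, (2) takes the global maximum of the correlation as the next
#' cell centroid (stopping when it falls below `stop_threshold` or after
#' `max_iterations`), (3) zeroes the probability map over a ball around
#' the accepted centroid so the same cell is not selected twice, and
#' (4) updates the correlation. The correlation update is an exact local
#' subtraction, so results are identical to recomputing the full
#' correlation each round. Ties at the maximum (within 1e-9) are broken
#' by the smallest `(z, y, x)` lexicographic index.
#'
#' Detections whose centroid lies within a template radius of a volume
#' face are flagged `edge` (evaluation and block merging treat them
#' specially); detection scores are non-increasing.
#'
#' @param p_cell Cell probability map: 3D array in `[0, 1]`, a
#'   [prob_maps()] object (its `cell` map is used), or an
#'   [image_volume()].
#' @param params A [detection_params()] list.
#' @param voxel_size_um,origin_um Geometry used to report physical
#'   centroids (taken from `p_cell` when it carries them).
#' @return A data frame of detections, one row per cell, with 0-based
#'   voxel indices (`z_vox`, `y_vox`, `x_vox`), physical coordinates
#'   (`x_um`, `y_um`, `z_um`), `score`, `diameter_um` (`NA` until
#'   [estimate_cell_sizes()] is run) and `edge`.
#' @export
detect_cells <- function(p_cell, params = detection_params(),
                         voxel_size_um = NULL, origin_um = NULL) {
  if (inherits(p_cell, "prob_maps")) {
    if (is.null(voxel_size_um)) voxel_size_um <- p_cell$voxel_size_um
    if (is.null(origin_um)) origin_um <- p_cell$origin_um
    p_cell <- p_cell$cell
  } else if (inherits(p_cell, "image_volume")) {
    if (is.null(voxel_size_um)) voxel_size_um <- p_cell$voxel_size_um
    if (is.null(origin_um)) origin_um <- p_cell$origin_um
    p_cell <- p_cell$data
  }
  if (is.null(voxel_size_um)) voxel_size_um <- 0.65
  if (is.null(origin_um)) origin_um <- c(0, 0, 0)
  stopifnot(inherits(params, "detection_params"))
  if (min(p_cell) < 0 || max(p_cell) > 1)
    stop("`p_cell` must lie in [0, 1]")
  d <- dim(p_cell)
  tmpl <- make_template(params$cell_size_vox)
  R <- max(abs(tmpl$offsets))
  zoff <- ball_offsets(params$zero_out_diameter_vox / 2)

  P <- p_cell + 0   # private copies: the C++ update writes in place
  if (!is.null(params$pre_threshold)) P[P < params$pre_threshold] <- 0
  corr <- correlate(P, tmpl) + 0

  zs <- ys <- xs <- integer(0)
  sc <- numeric(0)
  for (it in seq_len(params$max_iterations)) {
    am <- argmax_lex_cpp(corr, d, 1e-9)
    if (am$value < params$stop_threshold) break
    ctr <- am$index
    zs <- c(zs, ctr[1]); ys <- c(ys, ctr[2]); xs <- c(xs, ctr[3])
    sc <- c(sc, corr[ctr[1] + 1, ctr[2] + 1, ctr[3] + 1])
    zero_ball_update_cpp(P, corr, d, ctr, zoff, tmpl$offsets, tmpl$weight)
  }
  um <- vox_to_um(cbind(zs, ys, xs), voxel_size_um, origin_um)
  edge <- zs < R | ys < R | xs < R |
    zs > d[1] - 1 - R | ys > d[2] - 1 - R | xs > d[3] - 1 - R
  out <- data.frame(z_vox = zs, y_vox = ys, x_vox = xs,
                    x_um = um[, 3], y_um = um[, 2], z_um = um[, 1],
                    score = sc, diameter_um = rep(NA_real_, length(zs)),
                    edge = as.logical(edge))
  attr(out, "params") <- params
  attr(out, "voxel_size_um") <- voxel_size_um
  attr(out, "origin_um") <- origin_um
  class(out) <- c("cell_detections", "data.frame")
  out
}

#' Estimate a cell's diameter from the correlation growth curve
#'
#' Holds the centroid fixed and correlates spherical templates of
#' increasing diameter with the probability map. While the template can
#' still be inscribed in the cell body the correlation stays high; once
#' it outgrows the cell the correlation drops sharply. The estimate is
#' the diameter just before the largest forward decrease
#' `c(d) - c(d + 1)`. A flat curve (no drop) returns `d_min` with
#' `degenerate = TRUE`; a window that extends outside the volume is
#' truncated, renormalized and flagged `truncated`.
#'
#' @param p_cell Cell probability map (array, `prob_maps`, or volume).
#' @param centroid_vox 0-based `(z, y, x)` voxel index of the cell
#'   center.
#' @param d_min,d_max Diameter sweep bounds in voxels (step 1).
#' @param voxel_size_um Voxel size used to convert the estimate to um.
#' @return List with `diameter_vox`, `diameter_um`, `degenerate`,
#'   `truncated` and the `profile` data frame (`d`, `corr`).
#' @export
estimate_cell_size <- function(p_cell, centroid_vox, d_min = 4L, d_max = 30L,
                               voxel_size_um = 0.65) {
  if (inherits(p_cell, "prob_maps")) {
    voxel_size_um <- p_cell$voxel_size_um
    p_cell <- p_cell$cell
  } else {
    p_cell <- as_vol_array(p_cell)
  }
  if (d_min >= d_max) stop("`d_min` must be < `d_max`")
  d <- dim(p_cell)
  ctr <- as.integer(centroid_vox)
  if (any(ctr < 0) || any(ctr >= d)) stop("centroid outside volume")
  ds <- seq.int(d_min, d_max)
  cc <- numeric(length(ds))
  truncated <- FALSE
  for (i in seq_along(ds)) {
    off <- ball_offsets(ds[i] / 2)
    bs <- ball_sum_cpp(p_cell, d, ctr, off)
    if (bs$n_inside < nrow(off)) truncated <- TRUE
    cc[i] <- bs$sum / bs$n_inside
  }
  drops <- cc[-length(cc)] - cc[-1]
  if (max(drops) <= 1e-12) {
    est <- ds[1]
    degenerate <- TRUE
  } else {
    est <- ds[which.max(drops)]
    degenerate <- FALSE
  }
  list(diameter_vox = est, diameter_um = est * voxel_size_um,
       degenerate = degenerate, truncated = truncated,
       profile = data.frame(d = ds, corr = cc))
}

#' Fill in diameter estimates for a detection table
#'
#' Runs [estimate_cell_size()] at every detected centroid and writes the
#' result into the `diameter_um` column.
#'
#' @param p_cell Cell probability map.
#' @param detections A `cell_detections` data frame.
#' @inheritParams estimate_cell_size
#' @return The detection table with `diameter_um` filled.
#' @export
estimate_cell_sizes <- function(p_cell, detections, d_min = 4L, d_max = 30L) {
  vs <- attr(detections, "voxel_size_um")
  if (is.null(vs)) vs <- 0.65
  if (nrow(detections) == 0L) return(detections)
  for (i in seq_len(nrow(detections))) {
    ctr <- c(detections$z_vox[i], detections$y_vox[i], detections$x_vox[i])
    detections$diameter_um[i] <-
      estimate_cell_size(p_cell, ctr, d_min, d_max, vs)$diameter_um
  }
  detections
}
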