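#' Plan a block decomposition of a volume
#'
#' Tiles the volume with non-overlapping cores of `block_shape`
#' (truncated at the high faces); every voxel belongs to exactly one
#' core. Blocks are processed in lexicographic `(z, y, x)` core-origin
#' order. Each block is later read with `pad_vox` voxels of context per
#' face (truncated at the volume boundary); for cell detection the pad
#' must be at least the template diameter so per-block results agree
#' with an unblocked run.
#'
#' @param volume_shape Volume extents `(nz, ny, nx)` in voxels.
#' @param block_shape Core extents in voxels (componentwise
#'   `<= volume_shape`).
#' @param pad_vox Context pad per face, in voxels.
#' @return A `block_plan`: data frame with 0-based core origins
#'   (`z0, y0, x0`) and core shapes (`sz, sy, sx`); attributes
#'   `volume_shape`, `pad_vox`.
#' @export
plan_blocks <- function(volume_shape, block_shape, pad_vox = 0L) {
  volume_shape <- as.integer(volume_shape)
  block_shape <- as.integer(rep(block_shape, length.out = 3))
  if (any(block_shape < 1)) stop("block dimensions must be >= 1")
  if (any(block_shape > volume_shape))
    stop("block_shape must not exceed volume_shape")
  starts <- lapply(1:3, function(a) seq.int(0L, volume_shape[a] - 1L,
                                            by = block_shape[a]))
  g <- expand.grid(x0 = starts[[3]], y0 = starts[[2]], z0 = starts[[1]])
  g <- g[order(g$z0, g$y0, g$x0), , drop = FALSE]
  plan <- data.frame(z0 = g$z0, y0 = g$y0, x0 = g$x0)
  plan$sz <- pmin(block_shape[1], volume_shape[1] - plan$z0)
  plan$sy <- pmin(block_shape[2], volume_shape[2] - plan$y0)
  plan$sx <- pmin(block_shape[3], volume_shape[3] - plan$x0)
  rownames(plan) <- NULL
  attr(plan, "volume_shape") <- volume_shape
  attr(plan, "pad_vox") <- as.integer(pad_vox)
  class(plan) <- c("block_plan", "data.frame")
  plan
}

#' Merge per-block detections into a single detection set
#'
#' Processes blocks in plan order. A detection is kept only if its
#' centroid lies inside its own block's core (a deterministic ownership
#' rule: detections in the pad belong to the neighbouring block) and if
#' it is not within `overlap_dist_um` of an already-accepted detection
#' (duplicates arising from pad overlap). Edge flags are recomputed with
#' respect to the global volume. With pad at least the template
#' diameter, the merged result is independent of the blocking.
#'
#' @param per_block List of `cell_detections` data frames in *global*
#'   coordinates, one per plan row (same order).
#' @param plan A [plan_blocks()] plan.
#' @param overlap_dist_um Duplicate-suppression radius (default 10 um,
#'   the centroid matching radius).
#' @param template_radius_vox Radius used to recompute global edge
#'   flags.
#' @param voxel_size_um,origin_um Geometry of the global volume.
#' @return A merged `cell_detections` data frame.
#' @export
merge_detections <- function(per_block, plan, overlap_dist_um = 10,
                             template_radius_vox = 0L,
                             voxel_size_um = 0.65, origin_um = c(0, 0, 0)) {
  stopifnot(length(per_block) == nrow(plan))
  vol_shape <- attr(plan, "volume_shape")
  acc <- NULL
  for (b in seq_len(nrow(plan))) {
    det <- per_block[[b]]
    if (is.null(det) || nrow(det) == 0L) next
    core_lo <- c(plan$z0[b], plan$y0[b], plan$x0[b])
    core_hi <- core_lo + c(plan$sz[b], plan$sy[b], plan$sx[b])
    vox <- as.matrix(det[, c("z_vox", "y_vox", "x_vox")])
    in_core <- vox[, 1] >= core_lo[1] & vox[, 1] < core_hi[1] &
      vox[, 2] >= core_lo[2] & vox[, 2] < core_hi[2] &
      vox[, 3] >= core_lo[3] & vox[, 3] < core_hi[3]
    det <- det[in_core, , drop = FALSE]
    if (nrow(det) == 0L) next
    for (i in seq_len(nrow(det))) {
      if (!is.null(acc) && nrow(acc) > 0L) {
        dd <- sqrt((acc$x_um - det$x_um[i])^2 + (acc$y_um - det$y_um[i])^2 +
                     (acc$z_um - det$z_um[i])^2)
        if (min(dd) <= overlap_dist_um) next
      }
      acc <- rbind(acc, det[i, , drop = FALSE])
    }
  }
  if (is.null(acc))
    acc <- data.frame(z_vox = integer(0), y_vox = integer(0),
                      x_vox = integer(0), x_um = numeric(0),
                      y_um = numeric(0), z_um = numeric(0),
                      score = numeric(0), diameter_um = numeric(0),
                      edge = logical(0))
  R <- template_radius_vox
  acc$edge <- acc$z_vox < R | acc$y_vox < R | acc$x_vox < R |
    acc$z_vox > vol_shape[1] - 1 - R |
    acc$y_vox > vol_shape[2] - 1 - R |
    acc$x_vox > vol_shape[3] - 1 - R
  rownames(acc) <- NULL
  attr(acc, "voxel_size_um") <- voxel_size_um
  attr(acc, "origin_um") <- origin_um
  class(acc) <- c("cell_detections", "data.frame")
  acc
}

#' Block-wise cell detection
#'
#' Runs [detect_cells()] on padded blocks of a (possibly large) cell
#' probability map and merges the per-block results with
#' [merge_detections()].
#'
#' @param p_cell Cell probability map (array, `prob_maps` or volume).
#' @param params A [detection_params()].
#' @param block_shape Core shape in voxels.
#' @param pad_vox Pad per face; defaults to twice the template diameter.
#' @param voxel_size_um,origin_um Geometry.
#' @return A merged `cell_detections` data frame.
#' @export
detect_cells_blocked <- function(p_cell, params = detection_params(),
                                 block_shape, pad_vox = NULL,
                                 voxel_size_um = NULL, origin_um = NULL) {
  if (inherits(p_cell, "prob_maps")) {
    if (is.null(voxel_size_um)) voxel_size_um <- p_cell$voxel_size_um
    if (is.null(origin_um)) origin_um <- p_cell$origin_um
    p_cell <- p_cell$cell
  } else {
    p_cell <- as_vol_array(p_cell)
  }
  if (is.null(voxel_size_um)) voxel_size_um <- 0.65
  if (is.null(origin_um)) origin_um <- c(0, 0, 0)
  if (is.null(pad_vox)) pad_vox <- 2L * params$cell_size_vox
  vol <- image_volume(p_cell, voxel_size_um, origin_um)
  plan <- plan_blocks(dim(p_cell), block_shape, pad_vox)
  per_block <- vector("list", nrow(plan))
  for (b in seq_len(nrow(plan))) {
    blk <- extract_block(vol, c(plan$z0[b], plan$y0[b], plan$x0[b]),
                         c(plan$sz[b], plan$sy[b], plan$sx[b]), pad_vox)
    det <- detect_cells(blk$data, params, voxel_size_um, blk$origin_um)
    # local -> global voxel indices
    det$z_vox <- det$z_vox + blk$block_origin[1]
    det$y_vox <- det$y_vox + blk$block_origin[2]
    det$x_vox <- det$x_vox + blk$block_origin[3]
    per_block[[b]] <- det
  }
  merge_detections(per_block, plan, overlap_dist_um = 10,
                   template_radius_vox = max(abs(make_template(params$cell_size_vox)$offsets)),
                   voxel_size_um = voxel_size_um, origin_um = origin_um)
}
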