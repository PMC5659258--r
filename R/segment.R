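#' Vessel segmentation by probability-map morphology
#'
#' Binarizes the vessel probability map at `threshold`, dilates with a
#' Euclidean ball structuring element, labels connected components and
#' removes components smaller than `min_component_vox`. Components are
#' renumbered `1..K` by decreasing voxel count. Defaults reflect the
#' tuned vessel operating point (threshold 0.47, dilation radius 8
#' voxels).
#'
#' @param p_vessel Vessel probability map: 3D array in `[0, 1]`, a
#'   [prob_maps()] object (its `vessel` map) or an [image_volume()].
#' @param threshold Probability cutoff in `(0, 1)`; voxels with
#'   `p >= threshold` are kept.
#' @param dilation_radius_vox Ball radius for binary dilation (voxels).
#' @param min_component_vox Minimum component size in voxels.
#' @param connectivity Voxel connectivity: 6, 18 or 26 (default).
#' @return A [label_volume()] of vessel components.
#' @export
segment_vessels <- function(p_vessel, threshold = 0.47,
                            dilation_radius_vox = 8, min_component_vox = 0,
                            connectivity = 26) {
  vs <- 0.65; og <- c(0, 0, 0)
  if (inherits(p_vessel, "prob_maps")) {
    vs <- p_vessel$voxel_size_um; og <- p_vessel$origin_um
    p_vessel <- p_vessel$vessel
  } else if (inherits(p_vessel, "image_volume")) {
    vs <- p_vessel$voxel_size_um; og <- p_vessel$origin_um
    p_vessel <- p_vessel$data
  }
  check_morph_params(threshold, dilation_radius_vox, min_component_vox,
                     connectivity)
  mask <- p_vessel >= threshold
  mask <- binary_dilate_ball(mask, dilation_radius_vox)
  label_components(mask, dim(p_vessel), connectivity, min_component_vox,
                   vs, og)
}

#' Axon segmentation by thresholding and morphological opening
#'
#' Keeps voxels whose axon probability is at least `threshold` (voxels
#' below it are discarded), applies a morphological opening (erosion
#' then dilation) with a spherical structuring element, and labels the
#' surviving connected components with distinct IDs. Opening removes
#' structures thinner than the structuring element while preserving the
#' shape of thicker tubes.
#'
#' @param p_axon Axon probability map (array, `prob_maps` with an `axon`
#'   map, or volume).
#' @param threshold Probability cutoff (default 0.3).
#' @param se_radius_vox Ball radius of the structuring element, in
#'   voxels (default 4).
#' @param min_component_vox Minimum component size (default 0).
#' @param connectivity 6, 18 or 26.
#' @return A [label_volume()] of axon components.
#' @export
segment_axons <- function(p_axon, threshold = 0.3, se_radius_vox = 4,
                          min_component_vox = 0, connectivity = 26) {
  vs <- 0.65; og <- c(0, 0, 0)
  if (inherits(p_axon, "prob_maps")) {
    vs <- p_axon$voxel_size_um; og <- p_axon$origin_um
    if (is.null(p_axon$axon)) stop("probability maps carry no axon class")
    p_axon <- p_axon$axon
  } else if (inherits(p_axon, "image_volume")) {
    vs <- p_axon$voxel_size_um; og <- p_axon$origin_um
    p_axon <- p_axon$data
  }
  check_morph_params(threshold, se_radius_vox, min_component_vox,
                     connectivity)
  mask <- p_axon >= threshold
  mask <- binary_dilate_ball(binary_erode_ball(mask, se_radius_vox),
                             se_radius_vox)
  label_components(mask, dim(p_axon), connectivity, min_component_vox,
                   vs, og)
}

check_morph_params <- function(threshold, radius, min_size, connectivity) {
  if (threshold <= 0 || threshold >= 1)
    stop("`threshold` must be in (0, 1)")
  if (radius < 0) stop("structuring-element radius must be >= 0")
  if (min_size < 0) stop("`min_component_vox` must be >= 0")
  if (!connectivity %in% c(6, 18, 26))
    stop("`connectivity` must be 6, 18 or 26")
  invisible(TRUE)
}

label_components <- function(mask, d, connectivity, min_component_vox,
                             voxel_size_um, origin_um) {
  lab <- label3d_cpp(mask, d, as.integer(connectivity))
  if (max(lab) > 0L) {
    sizes <- tabulate(lab)
    keep <- which(sizes >= max(min_component_vox, 1))
    # renumber 1..K by decreasing size; ties keep discovery order
    keep <- keep[order(-sizes[keep], keep)]
    remap <- integer(length(sizes))
    remap[keep] <- seq_along(keep)
    lab <- c(0L, remap)[lab + 1L]
  }
  dim(lab) <- d
  label_volume(lab, voxel_size_um, origin_um)
}

#' Fractional volume occupied by a segmentation
#'
#' @param mask A [label_volume()] or 3D array; nonzero voxels count as
#'   foreground.
#' @return Percentage of nonzero voxels, `100 * n_fg / n_total`.
#' @export
vascular_fraction <- function(mask) {
  arr <- as_vol_array(mask)
  if (length(arr) == 0L) stop("empty volume")
  100 * sum(arr > 0) / length(arr)
}
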