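#' Squared distance to the k-th nearest neighbour
#'
#' `rho_k(x, A)`: the squared Euclidean distance from `x` to its k-th
#' nearest point in `A`. If `x` coincides exactly with a row of `A`,
#' that one point is excluded (leave-self-out).
#'
#' @param x Numeric length-3 position `(x, y, z)` in um.
#' @param A Matrix (n x 3) of positions in um.
#' @param k Neighbour index, `1 <= k <=` number of usable points.
#' @return Squared distance in um^2.
#' @export
knn_sq_distance <- function(x, A, k = 1L) {
  A <- as.matrix(A)
  x <- as.numeric(x)
  self <- which(A[, 1] == x[1] & A[, 2] == x[2] & A[, 3] == x[3])
  excl <- if (length(self) > 0L) self[1] - 1L else -1L
  n_avail <- nrow(A) - (excl >= 0L)
  if (k > n_avail) stop("`k` exceeds the number of available points")
  d2 <- knn_sq_cpp(matrix(x, 1, 3), A, as.integer(k), as.integer(excl))
  d2[1, k]
}

#' kNN density estimation over a 3D grid
#'
#' Nonparametric density estimate for a 3D point pattern (detected cell
#' centroids). At each grid-bin center `v` the unnormalized score is
#' `k / (N * rho_k(v, V))` where `rho_k` is the squared distance to the
#' k-th nearest centroid; scores are normalized over bins to a proper
#' probability mass function `p`, and converted to per-bin densities
#' `p_d(v) = p(v) * N / Vol * 1e9` in cells/mm^3 (`Vol` is the bin
#' volume in um^3). `rho_k` is clamped below at `(bin_side / 2)^2` so a
#' bin center coinciding with a centroid cannot absorb all mass.
#'
#' @param cells Matrix (N x 3) of centroid positions `(x, y, z)` in um,
#'   or a `cell_detections` data frame.
#' @param k Neighbour index (default 5; the estimator's only smoothing
#'   parameter).
#' @param bin_volume_um3 Bin volume in um^3 (default 8.44, i.e. bin side
#'   `8.44^(1/3) ~= 2.04` um — about one cell per bin).
#' @param bounds Optional list with `lo` and `hi` (length-3, um,
#'   `(x, y, z)`): the grid extent. Defaults to the centroid bounding
#'   box.
#' @return A `density_field`: list with `p` and `p_d` arrays (dims
#'   `(nx, ny, nz)` bins), `origin_um`, `bin_side_um`, `bin_volume_um3`,
#'   `k`, `N`.
#' @export
estimate_density <- function(cells, k = 5L, bin_volume_um3 = 8.44,
                             bounds = NULL) {
  V <- centroid_matrix(cells)
  N <- nrow(V)
  if (N <= k) stop("need more centroids than `k`")
  side <- bin_volume_um3^(1 / 3)
  if (is.null(bounds)) bounds <- list(lo = apply(V, 2, min),
                                      hi = apply(V, 2, max))
  lo <- as.numeric(bounds$lo); hi <- as.numeric(bounds$hi)
  nb <- pmax(1L, as.integer(ceiling((hi - lo) / side - 1e-9)))
  centers <- lapply(1:3, function(a) lo[a] + (seq_len(nb[a]) - 0.5) * side)
  grid <- as.matrix(expand.grid(x = centers[[1]], y = centers[[2]],
                                z = centers[[3]]))
  rho <- knn_sq_cpp(grid, V, as.integer(k),
                    rep.int(-1L, nrow(grid)))[, k]
  rho <- pmax(rho, (side / 2)^2)
  score <- k / (N * rho)
  p <- score / sum(score)
  p_d <- p * N / bin_volume_um3 * 1e9
  dim(p) <- nb
  dim(p_d) <- nb
  structure(list(p = p, p_d = p_d, origin_um = lo, bin_side_um = side,
                 bin_volume_um3 = bin_volume_um3, k = as.integer(k), N = N),
            class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  cat(sprintf("<density_field> %s bins of %.3g um, N = %d cells, k = %d\n",
              paste(dim(x$p), collapse = " x "), x$bin_side_um, x$N, x$k))
  cat(sprintf("  mean density %.4g cells/mm^3\n", mean(x$p_d)))
  invisible(x)
}

centroid_matrix <- function(cells) {
  if (is.data.frame(cells)) {
    stopifnot(all(c("x_um", "y_um", "z_um") %in% names(cells)))
    cells <- as.matrix(cells[, c("x_um", "y_um", "z_um")])
  }
  m <- as.matrix(cells)
  stopifnot(ncol(m) == 3L)
  dimnames(m) <- NULL
  m
}

#' Nearest-neighbour distance between cells
#'
#' For every cell, the Euclidean distance to its nearest other cell.
#'
#' @param cells Matrix (N x 3, um) or `cell_detections` data frame,
#'   N >= 2.
#' @return Numeric vector of N distances in um.
#' @export
cell_to_cell_distances <- function(cells) {
  V <- centroid_matrix(cells)
  if (nrow(V) < 2L) stop("need at least 2 cells")
  d2 <- knn_sq_cpp(V, V, 1L, seq_len(nrow(V)) - 1L)
  sqrt(d2[, 1])
}

#' Distance from each cell to the nearest vessel voxel
#'
#' Distances are measured from the cell centroid to the center of the
#' nearest nonzero vessel voxel, via a Euclidean distance transform
#' scaled by the voxel size. Centroids are snapped to the nearest voxel.
#'
#' @param cells Matrix (N x 3, um) or `cell_detections` data frame.
#' @param vessels A [label_volume()] (or 3D array) of vessels; nonzero
#'   voxels are vessel.
#' @param voxel_size_um,origin_um Geometry (taken from `vessels` when it
#'   is a `label_volume`).
#' @return Numeric vector of distances in um.
#' @export
cell_to_vessel_distances <- function(cells, vessels, voxel_size_um = 0.65,
                                     origin_um = c(0, 0, 0)) {
  if (inherits(vessels, "image_volume")) {
    voxel_size_um <- vessels$voxel_size_um
    origin_um <- vessels$origin_um
    vessels <- vessels$data
  }
  V <- centroid_matrix(cells)
  mask <- vessels > 0
  if (!any(mask)) stop("empty vessel mask")
  d <- dim(vessels)
  d2 <- edt3d_sq_cpp(mask, d)
  # (x, y, z) um -> (z, y, x) voxel
  vox <- um_to_vox(V[, c(3, 2, 1), drop = FALSE], voxel_size_um, origin_um)
  vox <- pmin(pmax(vox, 0), matrix(d - 1L, nrow(vox), 3, byrow = TRUE))
  lin <- voxel_linear_index(vox, d)
  sqrt(d2[lin]) * voxel_size_um
}

#' Summary statistics of a distance distribution
#'
#' @param distances Non-empty numeric vector (um).
#' @param bin_width_um Histogram bin width used for the mode (default
#'   1 um).
#' @return List with `mean`, `sd` (sample SD; 0 for a single value) and
#'   `mode` (center of the tallest histogram bin).
#' @export
summarize_distances <- function(distances, bin_width_um = 1) {
  if (length(distances) == 0L) stop("empty distance list")
  lo <- floor(min(distances) / bin_width_um) * bin_width_um
  breaks <- seq(lo, max(distances) + bin_width_um, by = bin_width_um)
  h <- graphics::hist(distances, breaks = breaks, plot = FALSE)
  list(mean = mean(distances),
       sd = if (length(distances) > 1L) stats::sd(distances) else 0,
       mode = h$mids[which.max(h$counts)])
}
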