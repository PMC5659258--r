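# Separable 3D filtering primitives used by the feature stack, the
# phantom generator and the morphology helpers. All boundary handling is
# by reflection.

gauss_kernel <- function(sigma, order = 0L) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  t <- (-r):r
  g <- exp(-t^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  # first-derivative correlation kernel, normalized to unit response on a
  # linear ramp
  k <- t * g
  k / sum(t * k)
}

conv_axis <- function(arr, kernel, axis) {
  out <- conv3d_axis_cpp(as.numeric(arr), dim(arr), kernel, axis - 1L)
  dim(out) <- dim(arr)
  out
}

#' Separable 3D Gaussian smoothing
#'
#' Smooths a 3D array (or [image_volume()]) with an isotropic Gaussian of
#' standard deviation `sigma_vox` voxels, using reflected boundaries.
#' `order` selects a plain Gaussian (0) or a Gaussian first derivative
#' (1) independently per axis, in `(z, y, x)` order.
#'
#' @param arr 3D array or [image_volume()].
#' @param sigma_vox Gaussian standard deviation in voxels.
#' @param order Integer vector of length 3, derivative order per axis.
#' @return 3D array of the same shape.
#' @export
gauss_blur3 <- function(arr, sigma_vox, order = c(0L, 0L, 0L)) {
  x <- as_vol_array(arr)
  if (sigma_vox <= 0) stop("`sigma_vox` must be positive")
  for (ax in 1:3) {
    x <- conv_axis(x, gauss_kernel(sigma_vox, order[ax]), ax)
  }
  x
}

# Gradient components (d/dz, d/dy, d/dx) at Gaussian scale sigma, in
# voxel units.
gauss_gradient3 <- function(arr, sigma_vox) {
  list(gz = gauss_blur3(arr, sigma_vox, c(1L, 0L, 0L)),
       gy = gauss_blur3(arr, sigma_vox, c(0L, 1L, 0L)),
       gx = gauss_blur3(arr, sigma_vox, c(0L, 0L, 1L)))
}

# Ball of 0-based integer offsets with Euclidean norm <= radius, as an
# n x 3 integer matrix in (z, y, x) columns.
ball_offsets <- function(radius) {
  r <- floor(radius + 1e-9)
  s <- (-r):r
  g <- as.matrix(expand.grid(z = s, y = s, x = s))
  keep <- rowSums(g^2) <= radius^2 + 1e-9
  m <- g[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

# Exact binary morphology with a Euclidean ball structuring element,
# built on the squared distance transform.
binary_dilate_ball <- function(mask, radius_vox) {
  mask <- mask > 0
  if (radius_vox <= 0 || !any(mask)) return(mask)
  d2 <- edt3d_sq_cpp(mask, dim(mask))
  out <- d2 <= radius_vox^2 + 1e-9
  dim(out) <- dim(mask)
  out
}

binary_erode_ball <- function(mask, radius_vox) {
  mask <- mask > 0
  if (radius_vox <= 0) return(mask)
  !binary_dilate_ball(!mask, radius_vox)
}
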