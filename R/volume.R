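#' Image volumes
#'
#' An `image_volume` is a 3D numeric array in `(z, y, x)` order together
#' with an isotropic voxel size in micrometres and a physical origin.
#' The physical coordinate (in um) of the 0-based voxel index `(i, j, k)`
#' (z, y, x) is `origin_um + voxel_size_um * c(i, j, k)`.
#'
#' @param data 3D numeric array, dimensions `(nz, ny, nx)`.
#' @param voxel_size_um Positive isotropic voxel size in micrometres
#'   (default 0.65, a typical synchrotron microCT pixel size).
#' @param origin_um Physical offset of voxel `(0, 0, 0)` in um, in
#'   `(z, y, x)` order.
#' @return An `image_volume` object.
#' @export
image_volume <- function(data, voxel_size_um = 0.65, origin_um = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array in (z, y, x) order")
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      voxel_size_um <= 0)
    stop("`voxel_size_um` must be a positive scalar")
  if (length(origin_um) != 3L) stop("`origin_um` must have length 3")
  structure(list(data = data,
                 voxel_size_um = as.numeric(voxel_size_um),
                 origin_um = as.numeric(origin_um)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels (z,y,x), %.3g um/voxel\n",
              d[1], d[2], d[3], x$voxel_size_um))
  cat(sprintf("  origin (um): %s; intensity range [%.4g, %.4g]\n",
              paste(signif(x$origin_um, 4), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Labelled segmentation volumes
#'
#' A `label_volume` wraps a 3D non-negative integer array with the same
#' geometry conventions as [image_volume()]. 0 is background; positive
#' integers label connected objects.
#'
#' @param data 3D integer array.
#' @param voxel_size_um,origin_um Geometry, as for [image_volume()].
#' @param label_names Optional named character vector mapping label id to
#'   class name.
#' @return A `label_volume` object.
#' @export
label_volume <- function(data, voxel_size_um = 0.65, origin_um = c(0, 0, 0),
                         label_names = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(data < 0)) stop("labels must be non-negative")
  storage.mode(data) <- "integer"
  v <- image_volume(data, voxel_size_um, origin_um)
  v$label_names <- label_names
  class(v) <- c("label_volume", "image_volume")
  v
}

as_vol_array <- function(x) {
  if (inherits(x, "image_volume")) x$data else x
}

#' Physical coordinates of voxel indices
#'
#' Converts 0-based `(z, y, x)` voxel indices to physical um coordinates
#' and back.
#'
#' @param idx Matrix (n x 3) or vector of 0-based voxel indices, columns
#'   `(z, y, x)`.
#' @param voxel_size_um Voxel size in um.
#' @param origin_um Origin in um, `(z, y, x)` order.
#' @return `vox_to_um()`: matrix of um coordinates in `(z, y, x)` column
#'   order; `um_to_vox()`: matrix of nearest 0-based voxel indices.
#' @export
vox_to_um <- function(idx, voxel_size_um, origin_um = c(0, 0, 0)) {
  idx <- rbind(idx)
  sweep(idx * voxel_size_um, 2, origin_um, "+")
}

#' @rdname vox_to_um
#' @export
um_to_vox <- function(idx, voxel_size_um, origin_um = c(0, 0, 0)) {
  idx <- rbind(idx)
  round(sweep(idx, 2, origin_um, "-") / voxel_size_um)
}

#' Read an image volume from a TIFF stack
#'
#' Reads either a multi-page TIFF file or a directory of single-slice
#' TIFF files (sorted by file name). Slice order in the file(s) becomes
#' the z axis.
#'
#' @param path File or directory path.
#' @param format Only `"tiff_stack"` is supported; volumes exported from
#'   HDF5-based acquisition pipelines should be converted to TIFF first.
#' @param voxel_size_um,origin_um Geometry metadata to attach.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, format = c("tiff_stack"), voxel_size_um = 0.65,
                        origin_um = c(0, 0, 0)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path)
  # 32-bit samples are floats and must not be reinterpreted as integers
  read_one <- function(f, all = FALSE) {
    float <- tiff::readTIFF(f, payload = FALSE)$bits.per.sample[1] == 32L
    tiff::readTIFF(f, all = all, as.is = !float)
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (length(files) == 0L) stop("no TIFF files found in ", path)
    slices <- lapply(files, read_one)
  } else {
    slices <- read_one(path, all = TRUE)
    if (is.matrix(slices)) slices <- list(slices)
  }
  shapes <- vapply(slices, dim, integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("inconsistent slice shapes in TIFF stack")
  nz <- length(slices)
  arr <- array(0, dim = c(nz, shapes[1, 1], shapes[2, 1]))
  for (i in seq_len(nz)) arr[i, , ] <- slices[[i]]
  image_volume(arr, voxel_size_um, origin_um)
}

#' Write an image volume as a multi-page TIFF
#'
#' Integer volumes with values in 0..255 (or 0..65535) are written as
#' 8-bit (16-bit) samples and round-trip exactly through [read_volume()].
#' Other numeric volumes are written as 32-bit float.
#'
#' @param vol An [image_volume()] or [label_volume()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  arr <- as_vol_array(vol)
  nz <- dim(arr)[1]
  is_int <- all(arr == round(arr)) && min(arr) >= 0
  if (is_int && max(arr) <= 255) {
    bps <- 8L; scale <- 255
  } else if (is_int && max(arr) <= 65535) {
    bps <- 16L; scale <- 65535
  } else {
    bps <- 32L; scale <- 1
  }
  slices <- lapply(seq_len(nz), function(i) {
    m <- array(arr[i, , , drop = FALSE], dim = dim(arr)[2:3])
    if (scale != 1) m / scale else m
  })
  tiff::writeTIFF(slices, path, bits.per.sample = bps,
                  reduce = FALSE, compression = "none")
  invisible(path)
}

#' Convert a volume to 8-bit depth
#'
#' Linearly rescales the intensity range `[min, max]` to `[0, 255]` and
#' rounds to the nearest integer, mirroring the usual bit-depth reduction
#' applied to 32-bit microCT reconstructions. A constant volume carries
#' no contrast and maps to 0.
#'
#' @param vol An [image_volume()].
#' @return An [image_volume()] with integer values in 0..255.
#' @export
to_uint8 <- function(vol) {
  arr <- as_vol_array(vol)
  if (any(!is.finite(arr))) stop("volume contains NaN/Inf values")
  lo <- min(arr); hi <- max(arr)
  out <- if (hi > lo) round((arr - lo) / (hi - lo) * 255) else array(0, dim(arr))
  dim(out) <- dim(arr)
  v <- if (inherits(vol, "image_volume")) vol else image_volume(arr)
  v$data <- out
  v
}

#' Per-slice automatic contrast enhancement
#'
#' For each z slice, clips intensities at the `saturate_frac` and
#' `1 - saturate_frac` quantiles and rescales the clipped range to
#' `[0, 255]` (a percentile stretch). With `saturate_frac = 0` this
#' reduces to the per-slice linear min-max stretch of [to_uint8()].
#'
#' @param vol An [image_volume()].
#' @param saturate_frac Fraction of pixels saturated at each tail,
#'   in `[0, 0.5)`. Default 0.0035, a conventional autocontrast tail.
#' @return An [image_volume()] with integer values in 0..255.
#' @export
autocontrast <- function(vol, saturate_frac = 0.0035) {
  if (saturate_frac < 0 || saturate_frac >= 0.5)
    stop("`saturate_frac` must be in [0, 0.5)")
  arr <- as_vol_array(vol)
  if (any(!is.finite(arr))) stop("volume contains NaN/Inf values")
  out <- array(0, dim(arr))
  for (i in seq_len(dim(arr)[1])) {
    sl <- arr[i, , ]
    qs <- stats::quantile(sl, c(saturate_frac, 1 - saturate_frac),
                          names = FALSE)
    lo <- qs[1]; hi <- qs[2]
    if (hi > lo) {
      sl <- pmin(pmax(sl, lo), hi)
      out[i, , ] <- round((sl - lo) / (hi - lo) * 255)
    }
  }
  v <- if (inherits(vol, "image_volume")) vol else image_volume(arr)
  v$data <- out
  v
}

#' Extract a padded block from a volume
#'
#' Returns the core region plus up to `pad` voxels of context on each
#' face, truncated at the volume boundary. The returned block records the
#' core's global origin and the pad actually achieved per face, which the
#' block-wise pipeline uses to assign detections back to cores.
#'
#' @param vol An [image_volume()].
#' @param core_origin 0-based voxel index `(z, y, x)` of the core's low
#'   corner.
#' @param core_shape Core extents in voxels (half-open).
#' @param pad Requested pad in voxels (scalar or length 3).
#' @return An [image_volume()] with extra fields `core_origin`,
#'   `core_shape`, `pad_lo`, `pad_hi` (all voxels, global 0-based).
#' @export
extract_block <- function(vol, core_origin, core_shape, pad = 0L) {
  arr <- as_vol_array(vol)
  d <- dim(arr)
  core_origin <- as.integer(core_origin)
  core_shape <- as.integer(core_shape)
  pad <- as.integer(rep(pad, length.out = 3))
  if (any(core_origin < 0) || any(core_shape < 1) ||
      any(core_origin + core_shape > d))
    stop("core region lies outside the volume")
  lo <- pmax(core_origin - pad, 0L)
  hi <- pmin(core_origin + core_shape + pad, d)
  block <- arr[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3],
               drop = FALSE]
  vs <- if (inherits(vol, "image_volume")) vol$voxel_size_um else 0.65
  og <- if (inherits(vol, "image_volume")) vol$origin_um else c(0, 0, 0)
  out <- image_volume(block, vs, og + vs * lo)
  out$core_origin <- core_origin
  out$core_shape <- core_shape
  out$pad_lo <- core_origin - lo
  out$pad_hi <- hi - (core_origin + core_shape)
  out$block_origin <- lo
  out
}

#' Read and write cell-centroid tables
#'
#' Centroid tables are CSV files with header columns
#' `x_um, y_um, z_um, diameter_um, score`. Writing then reading a table
#' is lossless to the printed precision.
#'
#' @param detections Data frame with (at least) those five columns, e.g.
#'   from [detect_cells()].
#' @param path CSV file path.
#' @return `read_centroids()` returns a data frame with the five columns.
#' @export
write_centroids <- function(detections, path) {
  cols <- c("x_um", "y_um", "z_um", "diameter_um", "score")
  df <- as.data.frame(detections)
  for (cl in setdiff(cols, names(df))) df[[cl]] <- NA_real_
  utils::write.csv(df[, cols, drop = FALSE], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_centroids
#' @export
read_centroids <- function(path) {
  if (!file.exists(path)) stop("path does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("x_um", "y_um", "z_um", "diameter_um", "score")
  if (!all(cols %in% names(df)))
    stop("malformed centroid table: expected columns ",
         paste(cols, collapse = ", "))
  for (cl in cols) {
    v <- df[[cl]]
    if (!is.numeric(v) && !is.logical(v)) {
      suppressWarnings(num <- as.numeric(v))
      if (any(is.na(num) & !is.na(v) & v != "NA"))
        stop("malformed centroid table: non-numeric value in column ", cl)
      v <- num
    }
    df[[cl]] <- as.numeric(v)
  }
  df[, cols, drop = FALSE]
}
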