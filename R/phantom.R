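#' Specification for a synthetic microCT phantom
#'
#' The phantom emulates the appearance of metal-stained, plastic-embedded
#' cortex in synchrotron microCT: bright quasi-spherical cell bodies
#' (optionally with a brighter nucleus) on a darker background at a
#' realized interior/exterior contrast of about 4.6 dB, brighter tortuous
#' vessels, thin bright myelinated-axon cylinders, a smooth low-frequency
#' brightness field and additive Gaussian noise.
#'
#' @param shape_vox Volume shape `(nz, ny, nx)` in voxels.
#' @param voxel_size_um Isotropic voxel size (default 0.65 um).
#' @param n_cells Number of non-overlapping cells.
#' @param cell_diameter_um Mean and SD of the normal cell-diameter
#'   distribution (truncated at 6 um); default `c(12, 2)`.
#' @param nucleus Add a brighter nucleus ball at 0.4x the cell diameter.
#' @param n_vessels Number of tortuous vessel tubes.
#' @param vessel_radius_um Range of vessel radii (default 2-5 um).
#' @param vessel_step_sd SD (radians-like) of the per-step direction
#'   perturbation of the vessel random walk (tortuosity).
#' @param n_axons Number of thin, low-curvature axon cylinders.
#' @param axon_radius_um Axon radius (default 1 um).
#' @param target_snr_db Target cell interior/exterior SNR in dB
#'   (default 4.6, the contrast level measured in stained neocortex).
#' @param snr_tol_db Calibration tolerance (default 0.3 dB).
#' @param brightness_amplitude Relative amplitude of the multiplicative
#'   low-frequency brightness field (default 0.08).
#' @param brightness_corr_um Correlation length of the brightness field.
#' @param noise_sd Additive Gaussian noise SD on the `[0, 1]` intensity
#'   scale.
#' @param background_level Mean background intensity.
#' @param seed Integer seed; the phantom is a pure function of
#'   spec + seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape_vox = c(128L, 128L, 128L),
                         voxel_size_um = 0.65,
                         n_cells = 30L,
                         cell_diameter_um = c(12, 2),
                         nucleus = TRUE,
                         n_vessels = 3L,
                         vessel_radius_um = c(2, 5),
                         vessel_step_sd = 0.25,
                         n_axons = 5L,
                         axon_radius_um = 1,
                         target_snr_db = 4.6,
                         snr_tol_db = 0.3,
                         brightness_amplitude = 0.08,
                         brightness_corr_um = 20,
                         noise_sd = 0.04,
                         background_level = 0.35,
                         seed = 1L) {
  if (any(c(n_cells, n_vessels, n_axons) < 0)) stop("counts must be >= 0")
  if (cell_diameter_um[1] <= 0) stop("cell diameter must be positive")
  structure(as.list(environment()), class = "phantom_spec")
}

stamp_ball <- function(arr, center_vox, radius_vox, value) {
  off <- ball_offsets(radius_vox)
  pos <- sweep(off, 2, as.integer(round(center_vox)), "+")
  d <- dim(arr)
  ok <- pos[, 1] >= 0 & pos[, 1] < d[1] & pos[, 2] >= 0 & pos[, 2] < d[2] &
    pos[, 3] >= 0 & pos[, 3] < d[3]
  pos <- pos[ok, , drop = FALSE]
  arr[voxel_linear_index(pos, d)] <- value
  arr
}

ball_hits <- function(occupied, center_vox, radius_vox) {
  off <- ball_offsets(radius_vox)
  pos <- sweep(off, 2, as.integer(round(center_vox)), "+")
  d <- dim(occupied)
  ok <- pos[, 1] >= 0 & pos[, 1] < d[1] & pos[, 2] >= 0 & pos[, 2] < d[2] &
    pos[, 3] >= 0 & pos[, 3] < d[3]
  any(occupied[voxel_linear_index(pos[ok, , drop = FALSE], d)] > 0)
}

grow_tube <- function(d, radius_vox, step_sd, max_steps) {
  axis <- sample(1:3, 1)
  pos <- stats::runif(3, 0.15, 0.85) * d
  pos[axis] <- 1
  dir <- stats::rnorm(3, 0, 0.15)
  dir[axis] <- 1
  dir <- dir / sqrt(sum(dir^2))
  path <- matrix(0, max_steps, 3)
  n <- 0L
  while (n < max_steps && all(pos >= 0) && all(pos < d)) {
    n <- n + 1L
    path[n, ] <- pos
    dir <- dir + stats::rnorm(3, 0, step_sd)
    dir[axis] <- dir[axis] + 0.3   # drift keeps the tube crossing the volume
    dir <- dir / sqrt(sum(dir^2))
    pos <- pos + dir
  }
  path[seq_len(n), , drop = FALSE]
}

#' Generate a synthetic phantom volume with ground truth
#'
#' Places structures in order vessels, axons, cells (cells are rejected
#' if they would overlap anything already placed or another cell),
#' composes the intensity volume, multiplies by a smooth brightness
#' field, adds Gaussian noise, and calibrates the cell/background
#' contrast so the measured interior/exterior SNR (same marker protocol
#' as [compute_snr()]) hits the target within tolerance. Since zero-mean
#' noise leaves regional means unchanged, calibration acts on the cell
#' intensity level; the noise level itself is a free parameter of the
#' spec. Fully reproducible from `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom` list: `intensity` ([image_volume()]), `cells`
#'   (data frame of truth centroids: voxel indices, um coordinates,
#'   `diameter_um`), `masks` (list of `cells`, `vessels`, `axons`
#'   [label_volume()]s, pairwise disjoint), `snr` (the realized
#'   calibration measurement or `NULL`), and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- as.integer(spec$shape_vox)
  vs <- spec$voxel_size_um

  vessel_mask <- array(0L, d)
  if (spec$n_vessels > 0) for (i in seq_len(spec$n_vessels)) {
    r_vox <- stats::runif(1, spec$vessel_radius_um[1],
                          spec$vessel_radius_um[2]) / vs
    path <- grow_tube(d, r_vox, spec$vessel_step_sd, max_steps = 4L * max(d))
    for (s in seq_len(nrow(path)))
      vessel_mask <- stamp_ball(vessel_mask, path[s, ], r_vox, i)
  }

  axon_mask <- array(0L, d)
  if (spec$n_axons > 0) for (i in seq_len(spec$n_axons)) {
    r_vox <- spec$axon_radius_um / vs
    path <- grow_tube(d, r_vox, spec$vessel_step_sd / 4, max_steps = 4L * max(d))
    for (s in seq_len(nrow(path)))
      axon_mask <- stamp_ball(axon_mask, path[s, ], r_vox, i)
  }
  axon_mask[vessel_mask > 0] <- 0L

  occupied <- (vessel_mask > 0) + (axon_mask > 0)
  cell_mask <- array(0L, d)
  nucleus_mask <- array(0L, d)
  centers <- matrix(0, spec$n_cells, 3)
  diam_um <- numeric(spec$n_cells)
  if (spec$n_cells > 0) for (i in seq_len(spec$n_cells)) {
    placed <- FALSE
    for (try in seq_len(2000L)) {
      dia <- max(6, stats::rnorm(1, spec$cell_diameter_um[1],
                                 spec$cell_diameter_um[2]))
      r_vox <- dia / (2 * vs)
      m <- ceiling(r_vox)
      if (any(d - 1 - 2 * m < 0)) next
      ctr <- vapply(d, function(n) sample(seq(m, n - 1 - m), 1), 0)
      if (i > 1) {
        dd <- sqrt(colSums((t(centers[seq_len(i - 1), , drop = FALSE]) - ctr)^2))
        min_sep <- (diam_um[seq_len(i - 1)] + dia) / (2 * vs) + 1
        if (any(dd < min_sep)) next
      }
      if (ball_hits(occupied, ctr, r_vox + 1)) next
      centers[i, ] <- ctr
      diam_um[i] <- dia
      cell_mask <- stamp_ball(cell_mask, ctr, r_vox, i)
      if (spec$nucleus)
        nucleus_mask <- stamp_ball(nucleus_mask, ctr, 0.2 * dia / vs, i)
      occupied <- stamp_ball(occupied, ctr, r_vox, 1L)
      placed <- TRUE
      break
    }
    if (!placed) stop("infeasible cell placement after bounded retries")
  }

  # smooth multiplicative brightness field
  field <- array(stats::rnorm(prod(d)), d)
  field <- gauss_blur3(field, spec$brightness_corr_um / vs)
  if (stats::sd(field) > 0)
    field <- (field - mean(field)) / stats::sd(field)
  field <- 1 + spec$brightness_amplitude * field

  noise <- array(stats::rnorm(prod(d), 0, spec$noise_sd), d)

  # SNR markers for calibration (interior ball + exterior shell per cell)
  markers <- if (spec$n_cells > 0)
    snr_markers_from_truth(centers, diam_um, vs, occupied > 0, d,
                           n_samples = min(spec$n_cells, 30L))
  else NULL

  compose <- function(gain) {
    lvl <- array(spec$background_level, d)
    cell_lvl <- spec$background_level * gain
    lvl[cell_mask > 0] <- cell_lvl
    lvl[nucleus_mask > 0] <- 1.15 * cell_lvl
    lvl[axon_mask > 0] <- 1.15 * cell_lvl
    lvl[vessel_mask > 0] <- 1.3 * cell_lvl
    lvl * field + noise
  }

  gain <- 10^(spec$target_snr_db / 20)
  snr <- NULL
  if (spec$n_cells > 0) {
    for (it in 1:8) {
      intensity <- compose(gain)
      snr <- compute_snr(intensity, markers$interior, markers$exterior)
      if (abs(snr$mean_db - spec$target_snr_db) <= spec$snr_tol_db) break
      gain <- gain * 10^((spec$target_snr_db - snr$mean_db) / 20)
    }
  } else {
    intensity <- compose(gain)
  }

  cells <- data.frame(z_vox = centers[, 1], y_vox = centers[, 2],
                      x_vox = centers[, 3],
                      x_um = centers[, 3] * vs, y_um = centers[, 2] * vs,
                      z_um = centers[, 1] * vs,
                      diameter_um = diam_um)
  if (spec$n_cells == 0) cells <- cells[0, ]

  list(intensity = image_volume(intensity, vs),
       cells = cells,
       masks = list(cells = label_volume(cell_mask, vs),
                    vessels = label_volume(vessel_mask, vs),
                    axons = label_volume(axon_mask, vs)),
       snr = snr,
       spec = spec)
}

# Build interior/exterior SNR marker labels for sampled cells, mirroring
# the manual protocol: a small marker inside the cell and one just
# outside the membrane, avoiding other structures.
snr_markers_from_truth <- function(centers, diam_um, voxel_size_um,
                                   occupied, d, n_samples = 30L) {
  n <- min(nrow(centers), n_samples)
  interior <- array(0L, d)
  exterior <- array(0L, d)
  for (i in seq_len(n)) {
    r_vox <- diam_um[i] / (2 * voxel_size_um)
    interior <- stamp_ball(interior, centers[i, ], max(1, 0.4 * r_vox), i)
    shell_out <- ball_offsets(r_vox + 4)
    shell_in <- rowSums(shell_out^2) > (r_vox + 1.5)^2
    pos <- sweep(shell_out[shell_in, , drop = FALSE], 2,
                 as.integer(round(centers[i, ])), "+")
    ok <- pos[, 1] >= 0 & pos[, 1] < d[1] & pos[, 2] >= 0 & pos[, 2] < d[2] &
      pos[, 3] >= 0 & pos[, 3] < d[3]
    lin <- voxel_linear_index(pos[ok, , drop = FALSE], d)
    lin <- lin[!occupied[lin]]
    exterior[lin] <- i
  }
  list(interior = interior, exterior = exterior)
}

#' SNR sampling markers for a phantom
#'
#' Reconstructs the interior/exterior marker volumes used to measure a
#' phantom's realized cell SNR with [compute_snr()].
#'
#' @param ph A `phantom` from [generate_phantom()].
#' @param n_samples Number of cells to sample (default 30).
#' @return List with `interior` and `exterior` integer label arrays.
#' @export
snr_markers <- function(ph, n_samples = 30L) {
  centers <- as.matrix(ph$cells[, c("z_vox", "y_vox", "x_vox")])
  occupied <- (as_vol_array(ph$masks$cells) > 0) |
    (as_vol_array(ph$masks$vessels) > 0) |
    (as_vol_array(ph$masks$axons) > 0)
  snr_markers_from_truth(centers, ph$cells$diameter_um,
                         ph$intensity$voxel_size_um, occupied,
                         dim(as_vol_array(ph$intensity)), n_samples)
}

#' Probability maps from ground-truth masks
#'
#' Builds synthetic class probability maps directly from truth masks:
#' one-hot class volumes are Gaussian-blurred, renormalized to sum to 1
#' per voxel, and optionally corrupted by label-flip noise. This lets
#' detection and segmentation be exercised independently of the
#' classifier.
#'
#' @param masks List with `cells`, `vessels` (and optionally `axons`)
#'   [label_volume()]s or arrays, pairwise disjoint.
#' @param blur_sigma_vox Gaussian blur SD in voxels (0 = exact one-hot).
#' @param flip_noise Per-voxel probability of replacing the probability
#'   tuple by a random one-hot class (default 0).
#' @param include_axon Emit a 4-class map with an `axon` channel;
#'   otherwise axons (if present) are folded into `background`.
#' @param voxel_size_um Geometry for the returned maps.
#' @param seed Seed for the flip noise (only used when
#'   `flip_noise > 0`).
#' @return A [prob_maps()] object.
#' @export
probabilities_from_truth <- function(masks, blur_sigma_vox = 1,
                                     flip_noise = 0, include_axon = FALSE,
                                     voxel_size_um = 0.65, seed = 1L) {
  cell <- as_vol_array(masks$cells) > 0
  vessel <- as_vol_array(masks$vessels) > 0
  axon <- if (!is.null(masks$axons)) as_vol_array(masks$axons) > 0
  else array(FALSE, dim(cell))
  if (any(cell & vessel) || any(cell & axon) || any(vessel & axon))
    stop("truth masks must be pairwise disjoint")
  d <- dim(cell)
  onehot <- list(cell = cell + 0, vessel = vessel + 0)
  if (include_axon) {
    onehot$axon <- axon + 0
    onehot$background <- 1 - onehot$cell - onehot$vessel - onehot$axon
  } else {
    onehot$background <- 1 - onehot$cell - onehot$vessel
  }
  if (blur_sigma_vox > 0)
    onehot <- lapply(onehot, gauss_blur3, sigma_vox = blur_sigma_vox)
  tot <- Reduce(`+`, onehot)
  onehot <- lapply(onehot, function(m) {
    m <- m / tot
    dim(m) <- d
    m
  })
  if (flip_noise > 0) {
    set.seed(seed)
    nflip <- stats::rbinom(1, prod(d), flip_noise)
    idx <- sample.int(prod(d), nflip)
    cls <- sample.int(length(onehot), nflip, replace = TRUE)
    for (ci in seq_along(onehot)) {
      onehot[[ci]][idx] <- as.numeric(cls == ci)
    }
  }
  ord <- intersect(c("cell", "vessel", "background", "axon"), names(onehot))
  prob_maps(onehot[ord], voxel_size_um = voxel_size_um)
}

#' Sparse training annotations from phantom truth
#'
#' Samples voxel annotations per class from a phantom's ground truth,
#' emulating the sparse manual scribbles a classifier is trained from.
#'
#' @param ph A `phantom`.
#' @param n_per_class Voxels sampled per class (default 2000).
#' @param seed Sampling seed.
#' @param include_axon Annotate axons as their own class (otherwise they
#'   are left unlabeled).
#' @return Data frame with 0-based `z`, `y`, `x` and `class`, suitable
#'   for [train_classifier()].
#' @export
sample_annotations <- function(ph, n_per_class = 2000L, seed = 1L,
                               include_axon = FALSE) {
  set.seed(seed)
  d <- dim(as_vol_array(ph$intensity))
  cell <- as_vol_array(ph$masks$cells) > 0
  vessel <- as_vol_array(ph$masks$vessels) > 0
  axon <- as_vol_array(ph$masks$axons) > 0
  bg <- !(cell | vessel | axon)
  pick <- function(mask, cls) {
    idx <- which(mask)
    if (length(idx) == 0L) return(NULL)
    idx <- sample(idx, min(n_per_class, length(idx)))
    i0 <- idx - 1L
    data.frame(z = i0 %% d[1],
               y = (i0 %/% d[1]) %% d[2],
               x = i0 %/% (d[1] * d[2]),
               class = cls)
  }
  out <- rbind(pick(cell, "cell"), pick(vessel, "vessel"), pick(bg, "background"),
               if (include_axon) pick(axon, "axon"))
  out[sample.int(nrow(out)), , drop = FALSE]
}
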