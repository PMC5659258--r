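#' Multi-scale voxel features for pixel classification
#'
#' Computes, for every voxel and every Gaussian scale, the features that
#' drive the cell/vessel/background classifier: the gradient-of-Gaussian
#' magnitude, the difference of Gaussians (DoG, ratio 1.6), and the three
#' eigenvalues (sorted descending) of the structure tensor (outer product
#' of Gaussian gradients, smoothed at twice the scale). Raw intensity is
#' excluded by default: absolute brightness drifts across microCT samples
#' and makes classifiers brittle; it can be re-enabled for well
#' flat-fielded data.
#'
#' @param vol An [image_volume()] (intensities are internally normalized
#'   to `[0, 1]`).
#' @param scales_um Gaussian scales in micrometres. The default
#'   `c(0.65, 1.3, 2.6, 5.2)` spans nucleus-edge to soma scale at a
#'   0.65 um voxel size.
#' @param include_intensity Add the normalized raw intensity as a feature.
#' @return A `feature_stack`: list with `data` (voxel x feature matrix in
#'   array-linear order), `feature_names`, `scales_um`, `dim`,
#'   `voxel_size_um`, `include_intensity`.
#' @export
compute_features <- function(vol, scales_um = c(0.65, 1.3, 2.6, 5.2),
                             include_intensity = FALSE) {
  if (length(scales_um) == 0L || any(scales_um <= 0))
    stop("`scales_um` must be non-empty and positive")
  vs <- if (inherits(vol, "image_volume")) vol$voxel_size_um else 0.65
  arr <- as_vol_array(vol)
  d <- dim(arr)
  rng <- range(arr)
  v <- if (rng[2] > rng[1]) (arr - rng[1]) / (rng[2] - rng[1]) else arr * 0
  dim(v) <- d
  sig <- scales_um / vs
  if (any(sig < 0.5))
    warning("scales below half a voxel are under-resolved")
  if (any(d < 2 * ceiling(3 * max(sig)) + 1))
    warning("volume is thin relative to the largest kernel support")

  nfeat <- 5L * length(sig) + as.integer(include_intensity)
  X <- matrix(0, nrow = prod(d), ncol = nfeat)
  nm <- character(nfeat)
  j <- 0L
  for (si in seq_along(sig)) {
    s <- sig[si]
    g <- gauss_gradient3(v, s)
    gm <- sqrt(g$gz^2 + g$gy^2 + g$gx^2)
    dog <- gauss_blur3(v, s) - gauss_blur3(v, 1.6 * s)
    # structure tensor, component-wise smoothing at 2*s
    e <- eig3_sym_cpp(gauss_blur3(g$gz * g$gz, 2 * s),
                      gauss_blur3(g$gz * g$gy, 2 * s),
                      gauss_blur3(g$gz * g$gx, 2 * s),
                      gauss_blur3(g$gy * g$gy, 2 * s),
                      gauss_blur3(g$gy * g$gx, 2 * s),
                      gauss_blur3(g$gx * g$gx, 2 * s))
    block <- list(gm, dog, e$e1, e$e2, e$e3)
    lab <- c("gradmag", "dog", "st_ev1", "st_ev2", "st_ev3")
    for (b in seq_along(block)) {
      j <- j + 1L
      X[, j] <- as.numeric(block[[b]])
      nm[j] <- sprintf("%s_s%g", lab[b], scales_um[si])
    }
  }
  if (include_intensity) {
    j <- j + 1L
    X[, j] <- as.numeric(v)
    nm[j] <- "intensity"
  }
  colnames(X) <- nm
  structure(list(data = X, feature_names = nm, scales_um = scales_um,
                 dim = d, voxel_size_um = vs,
                 include_intensity = include_intensity),
            class = "feature_stack")
}

voxel_linear_index <- function(idx_zyx, d) {
  idx_zyx <- rbind(idx_zyx)
  if (any(idx_zyx < 0) || any(sweep(idx_zyx, 2, d, ">=")))
    stop("voxel indices out of bounds")
  1L + idx_zyx[, 1] + d[1] * (idx_zyx[, 2] + d[2] * idx_zyx[, 3])
}

feature_manifest <- function(features) {
  list(feature_names = features$feature_names,
       scales_um = features$scales_um,
       include_intensity = features$include_intensity)
}

#' Train the voxel random-forest classifier
#'
#' Fits a probability random forest on sparse voxel annotations. Class
#' order is fixed as (cell, vessel, background, axon) so that model files
#' and probability maps are portable; only classes present in `labels`
#' are used.
#'
#' @param features A `feature_stack` from [compute_features()].
#' @param labels Sparse annotations: data frame with 0-based voxel index
#'   columns `z`, `y`, `x` and a `class` column drawn from
#'   `c("cell", "vessel", "background", "axon")`.
#' @param n_trees Number of trees (default 100).
#' @param seed Integer seed; required, so training is reproducible.
#' @return A `cell_classifier` with the fitted forest and an embedded
#'   feature manifest.
#' @export
train_classifier <- function(features, labels, n_trees = 100L, seed) {
  if (missing(seed)) stop("`seed` is required for reproducible training")
  stopifnot(inherits(features, "feature_stack"))
  if (!all(c("z", "y", "x", "class") %in% names(labels)))
    stop("`labels` needs columns z, y, x, class")
  class_order <- c("cell", "vessel", "background", "axon")
  cls <- as.character(labels$class)
  if (!all(cls %in% class_order))
    stop("unknown class labels: ", paste(setdiff(cls, class_order), collapse = ", "))
  present <- class_order[class_order %in% unique(cls)]
  if (length(present) < 2L)
    stop("at least 2 classes must be present in the annotations")
  lin <- voxel_linear_index(as.matrix(labels[, c("z", "y", "x")]), features$dim)
  df <- as.data.frame(features$data[lin, , drop = FALSE])
  df$.class <- factor(cls, levels = present)
  fit <- ranger::ranger(dependent.variable.name = ".class", data = df,
                        num.trees = n_trees, probability = TRUE,
                        seed = seed, num.threads = 1L)
  structure(list(forest = fit, classes = present,
                 manifest = feature_manifest(features),
                 n_trees = n_trees, seed = seed),
            class = "cell_classifier")
}

#' @export
print.cell_classifier <- function(x, ...) {
  cat(sprintf("<cell_classifier> %d trees, classes: %s\n", x$n_trees,
              paste(x$classes, collapse = ", ")))
  cat(sprintf("  %d features at scales %s um\n",
              length(x$manifest$feature_names),
              paste(x$manifest$scales_um, collapse = ", ")))
  invisible(x)
}

#' Save / load a trained classifier
#'
#' The model file embeds the feature manifest; [predict_probabilities()]
#' refuses to apply a model whose manifest does not match the features it
#' is given.
#'
#' @param clf A `cell_classifier`.
#' @param path File path.
#' @export
save_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "cell_classifier"))
  saveRDS(clf, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  clf <- readRDS(path)
  if (!inherits(clf, "cell_classifier")) stop("not a cell_classifier file")
  clf
}

#' Per-voxel class probability maps
#'
#' Applies a trained classifier to a volume (or a precomputed
#' `feature_stack`) and returns one probability array per class. At every
#' voxel the class probabilities sum to 1.
#'
#' @param clf A `cell_classifier` from [train_classifier()].
#' @param vol An [image_volume()] or a `feature_stack`.
#' @return A `prob_maps` object: list with one 3D array per class
#'   (`cell`, `vessel`, `background`, optionally `axon`), plus `dim`,
#'   `voxel_size_um`, `origin_um`, `classes`.
#' @export
predict_probabilities <- function(clf, vol) {
  stopifnot(inherits(clf, "cell_classifier"))
  origin <- c(0, 0, 0)
  if (inherits(vol, "feature_stack")) {
    features <- vol
  } else {
    origin <- vol$origin_um
    features <- compute_features(vol, scales_um = clf$manifest$scales_um,
                                 include_intensity = clf$manifest$include_intensity)
  }
  if (!identical(features$feature_names, clf$manifest$feature_names))
    stop("feature manifest mismatch between classifier and input features")
  df <- as.data.frame(features$data)
  pred <- stats::predict(clf$forest, data = df, num.threads = 1L)$predictions
  pred <- pred[, clf$classes, drop = FALSE]
  out <- list()
  for (cl in clf$classes) {
    a <- pred[, cl]
    dim(a) <- features$dim
    out[[cl]] <- a
  }
  prob_maps(out, voxel_size_um = features$voxel_size_um, origin_um = origin)
}

#' Construct a probability-map set
#'
#' @param maps Named list of 3D arrays in `[0, 1]` (same shape), with at
#'   least `cell`, `vessel`, `background`; per-voxel sums must be 1
#'   within 1e-6.
#' @param voxel_size_um,origin_um Geometry.
#' @return A `prob_maps` object.
#' @export
prob_maps <- function(maps, voxel_size_um = 0.65, origin_um = c(0, 0, 0)) {
  stopifnot(is.list(maps), length(maps) >= 2L)
  d <- dim(maps[[1]])
  tot <- 0
  for (m in maps) {
    if (!identical(dim(m), d)) stop("probability maps must share one shape")
    tot <- tot + m
  }
  if (max(abs(tot - 1)) > 1e-6)
    stop("per-voxel class probabilities must sum to 1")
  structure(c(maps, list(dim = d, voxel_size_um = voxel_size_um,
                         origin_um = as.numeric(origin_um),
                         classes = names(maps))),
            class = "prob_maps")
}

#' @export
print.prob_maps <- function(x, ...) {
  cat(sprintf("<prob_maps> %s voxels (z,y,x); classes: %s\n",
              paste(x$dim, collapse = " x "),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}
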