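#' Weighted harmonic mean of precision and recall
#'
#' `f_beta = (1 + beta^2) * p * r / (beta^2 * p + r)`, with 0 returned
#' when the denominator is 0. `beta = 1` balances precision and recall;
#' `beta = 2` weights recall more heavily (used for vessel
#' segmentation).
#'
#' @param p,r Precision and recall in `[0, 1]` (vectorized).
#' @param beta Weight (default 1).
#' @return f_beta score(s).
#' @export
fbeta <- function(p, r, beta = 1) {
  den <- beta^2 * p + r
  ifelse(den > 0, (1 + beta^2) * p * r / den, 0)
}

#' Voxel-level precision / recall / f-beta
#'
#' Binarizes both volumes (nonzero = foreground) and counts voxelwise
#' true positives, false positives (detected but not in the manual
#' segmentation) and false negatives (manual but missed).
#'
#' @param pred,truth [label_volume()]s or 3D arrays of matching shape.
#' @param betas f-beta weights to report (default `c(1, 2)`).
#' @return A `pixel_eval` list: `tp`, `fp`, `fn`, `p`, `r`, and `f`
#'   (named vector, one entry per beta).
#' @export
pixel_eval <- function(pred, truth, betas = c(1, 2)) {
  a <- as_vol_array(pred) > 0
  b <- as_vol_array(truth) > 0
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  tp <- sum(a & b)
  fp <- sum(a & !b)
  fn <- sum(!a & b)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- vapply(betas, function(bb) fbeta(p, r, bb), 0)
  names(f) <- paste0("f", betas)
  structure(list(tp = tp, fp = fp, fn = fn, p = p, r = r, f = f),
            class = "pixel_eval")
}

#' Object-level centroid matching
#'
#' Pairs detected and true cell centroids: repeatedly take the globally
#' closest unmatched (detected, truth) pair; if their distance is within
#' `max_dist_um` record a match and remove both; stop when no pair
#' qualifies. Each centroid appears in at most one pair, and the result
#' does not depend on input ordering. Precision is matches / detected,
#' recall matches / truth.
#'
#' Because objects at the volume boundary are inherently ambiguous for
#' both human and automated annotators, centroids within
#' `edge_margin_um` of the boundary (given `bounds`) are dropped from
#' both sets before matching.
#'
#' @param detected,truth Matrices (n x 3, um, `(x, y, z)`) or
#'   `cell_detections` data frames in the same physical frame.
#' @param max_dist_um Match radius (default 10 um).
#' @param bounds Optional list `lo`, `hi` (length-3 um) defining the
#'   volume extent for edge exclusion.
#' @param edge_margin_um Exclusion margin (default 0: keep everything).
#' @return A `match_result` list: `pairs` (data frame of detected index,
#'   truth index, distance), `unmatched_detected`, `unmatched_truth`,
#'   `n_detected`, `n_truth`, `excluded_detected`, `excluded_truth`,
#'   `p`, `r`.
#' @export
match_centroids <- function(detected, truth, max_dist_um = 10,
                            bounds = NULL, edge_margin_um = 0) {
  if (max_dist_um < 0) stop("`max_dist_um` must be >= 0")
  D <- centroid_matrix(detected)
  Tm <- centroid_matrix(truth)
  exc_d <- exc_t <- 0L
  if (!is.null(bounds) && edge_margin_um > 0) {
    keep <- function(M) {
      if (nrow(M) == 0L) return(logical(0))
      apply(M, 1, function(v)
        all(v >= bounds$lo + edge_margin_um) &&
          all(v <= bounds$hi - edge_margin_um))
    }
    kd <- keep(D); kt <- keep(Tm)
    exc_d <- sum(!kd); exc_t <- sum(!kt)
    D <- D[kd, , drop = FALSE]
    Tm <- Tm[kt, , drop = FALSE]
  }
  nd <- nrow(D); nt <- nrow(Tm)
  pairs <- data.frame(detected = integer(0), truth = integer(0),
                      dist_um = numeric(0))
  if (nd > 0 && nt > 0) {
    dm2 <- outer(rowSums(D^2), rowSums(Tm^2), "+") - 2 * D %*% t(Tm)
    dm <- sqrt(pmax(dm2, 0))
    ord <- order(dm)
    used_d <- logical(nd); used_t <- logical(nt)
    for (o in ord) {
      if (dm[o] > max_dist_um) break
      i <- (o - 1) %% nd + 1
      j <- (o - 1) %/% nd + 1
      if (used_d[i] || used_t[j]) next
      used_d[i] <- TRUE; used_t[j] <- TRUE
      pairs <- rbind(pairs, data.frame(detected = i, truth = j,
                                       dist_um = sqrt(sum((D[i, ] - Tm[j, ])^2))))
    }
  }
  m <- nrow(pairs)
  structure(list(pairs = pairs,
                 unmatched_detected = setdiff(seq_len(nd), pairs$detected),
                 unmatched_truth = setdiff(seq_len(nt), pairs$truth),
                 n_detected = nd, n_truth = nt,
                 excluded_detected = exc_d, excluded_truth = exc_t,
                 p = if (nd > 0) m / nd else 0,
                 r = if (nt > 0) m / nt else 0),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d matches of %d detected / %d truth: (p, r) = (%.3f, %.3f)\n",
              nrow(x$pairs), x$n_detected, x$n_truth, x$p, x$r))
  invisible(x)
}

#' Cell signal-to-noise ratio from paired markers
#'
#' For each sampled cell `i` with an interior marker (mean intensity
#' `s_i`) and an exterior marker just outside the membrane (mean `n_i`),
#' `SNR_i = 20 * log10(s_i / n_i)` in dB.
#'
#' @param vol An [image_volume()] or 3D array.
#' @param interior,exterior Integer label arrays (or [label_volume()]s)
#'   sharing cell ids: id `i` marks the i-th cell's interior / exterior
#'   sample.
#' @return List with `samples` (data frame `id`, `s`, `n`, `snr_db`),
#'   `mean_db`, `sd_db`.
#' @export
compute_snr <- function(vol, interior, exterior) {
  arr <- as_vol_array(vol)
  li <- as_vol_array(interior)
  le <- as_vol_array(exterior)
  ids <- intersect(sort(unique(li[li > 0])), sort(unique(le[le > 0])))
  if (length(ids) == 0L) stop("no shared cell ids between markers")
  s <- vapply(ids, function(id) mean(arr[li == id]), 0)
  n <- vapply(ids, function(id) mean(arr[le == id]), 0)
  if (any(s <= 0) || any(n <= 0))
    stop("marker means must be positive to compute SNR in dB")
  snr <- 20 * log10(s / n)
  list(samples = data.frame(id = ids, s = s, n = n, snr_db = snr),
       mean_db = mean(snr),
       sd_db = if (length(snr) > 1L) stats::sd(snr) else 0)
}

#' Hyperparameter grid search
#'
#' Evaluates every row of `param_grid` and returns the best-scoring
#' parameters together with the full score table. Cells are scored by
#' running [detect_cells()] and matching centroids against truth
#' (objective `f1_cells`); vessels by [segment_vessels()] and voxelwise
#' f2 (`f2_vessels`, recall-weighted, which tracks visual quality better
#' for vessels). Ties are broken by the smallest threshold, then the
#' smallest cell size.
#'
#' @param param_grid Data frame of parameter combinations. For cells:
#'   columns `cell_size_vox` and `stop_threshold` (optional
#'   `zero_out_diameter_vox`). For vessels: `threshold`,
#'   `dilation_radius_vox`, `min_component_vox`.
#' @param prob_maps A [prob_maps()] object (or a bare probability array
#'   for the relevant class).
#' @param truth For cells: truth centroid matrix (um) or data frame.
#'   For vessels: truth [label_volume()] / mask array.
#' @param objective `"f1_cells"` or `"f2_vessels"`.
#' @param match_dist_um Centroid match radius (cells; default 10).
#' @param bounds,edge_margin_um Edge exclusion for centroid matching.
#' @return List with `best` (the argmax row), `best_score`, and `table`
#'   (the grid with a `score` column).
#' @export
grid_search <- function(param_grid, prob_maps, truth,
                        objective = c("f1_cells", "f2_vessels"),
                        match_dist_um = 10, bounds = NULL,
                        edge_margin_um = 0) {
  objective <- match.arg(objective)
  if (nrow(param_grid) == 0L) stop("empty parameter grid")
  scores <- numeric(nrow(param_grid))
  for (i in seq_len(nrow(param_grid))) {
    g <- param_grid[i, , drop = FALSE]
    if (objective == "f1_cells") {
      zo <- if ("zero_out_diameter_vox" %in% names(g))
        g$zero_out_diameter_vox else g$cell_size_vox
      det <- detect_cells(prob_maps,
                          detection_params(cell_size_vox = g$cell_size_vox,
                                           stop_threshold = g$stop_threshold,
                                           zero_out_diameter_vox = zo))
      mr <- match_centroids(det, truth, max_dist_um = match_dist_um,
                            bounds = bounds, edge_margin_um = edge_margin_um)
      scores[i] <- fbeta(mr$p, mr$r, 1)
    } else {
      seg <- segment_vessels(prob_maps, threshold = g$threshold,
                             dilation_radius_vox = g$dilation_radius_vox,
                             min_component_vox = g$min_component_vox)
      scores[i] <- pixel_eval(seg, truth, betas = 2)$f[["f2"]]
    }
  }
  tab <- cbind(param_grid, score = scores)
  thr_col <- if (objective == "f1_cells") "stop_threshold" else "threshold"
  size_col <- if (objective == "f1_cells") "cell_size_vox" else "dilation_radius_vox"
  ord <- order(-scores, param_grid[[thr_col]], param_grid[[size_col]])
  best <- ord[1]
  if (max(scores) <= 0)
    warning("all grid points scored 0; returning the first point")
  list(best = param_grid[best, , drop = FALSE], best_score = scores[best],
       table = tab)
}

#' Half-period resolution from a crossing frequency
#'
#' Converts the spatial frequency at which the signal power spectrum
#' drops to five times the noise power (the Rose detectability
#' criterion) into a half-period resolution `1 / (2 * f)`.
#'
#' @param f_cross Crossing frequency in 1/um.
#' @return Resolution in um.
#' @export
half_period_resolution <- function(f_cross) {
  if (any(f_cross <= 0)) stop("crossing frequency must be positive")
  1 / (2 * f_cross)
}

# Radially averaged 2D power spectrum of a stack of planes.
# planes: list of matrices (same shape). Returns data frame (freq, power)
# with freq in 1/um.
radial_power_spectrum <- function(planes, voxel_size_um) {
  d <- dim(planes[[1]])
  acc <- matrix(0, d[1], d[2])
  for (pl in planes) {
    f <- stats::fft(pl - mean(pl))
    acc <- acc + (Mod(f)^2) / length(pl)
  }
  acc <- acc / length(planes)
  f1 <- ifelse(seq_len(d[1]) - 1 <= d[1] / 2, seq_len(d[1]) - 1,
               seq_len(d[1]) - 1 - d[1]) / (d[1] * voxel_size_um)
  f2 <- ifelse(seq_len(d[2]) - 1 <= d[2] / 2, seq_len(d[2]) - 1,
               seq_len(d[2]) - 1 - d[2]) / (d[2] * voxel_size_um)
  fr <- sqrt(outer(f1^2, f2^2, "+"))
  df <- 1 / (max(d) * voxel_size_um)
  bin <- round(fr / df)
  agg <- tapply(as.numeric(acc), as.numeric(bin), mean)
  data.frame(freq = as.numeric(names(agg)) * df, power = as.numeric(agg))
}

#' Effective image resolution via the Rose criterion
#'
#' Estimates the effective resolution of a reconstructed volume from
#' averaged power spectra: a series of transverse (`xy`) and vertical
#' (`xz`) planes is taken from a signal region (tissue) and a background
#' region (no tissue); the radially averaged signal power spectrum (SPS)
#' is smoothed by fitting a second-order polynomial to its logarithm
#' over `band`, and the lowest frequency where the fitted SPS falls to
#' five times the noise power spectrum (NPS) defines the resolving
#' frequency; the half-period `1 / (2 * f)` is reported per orientation.
#'
#' @param signal An [image_volume()] containing tissue.
#' @param background An [image_volume()] of matching voxel size with no
#'   tissue (noise only).
#' @param n_planes Maximum number of planes to average per orientation
#'   (default 256).
#' @param band Frequency band (1/um) over which the polynomial is fitted
#'   and the crossing searched; default 0.05 to Nyquist.
#' @return List with one entry per orientation (`xy`, `xz`), each
#'   containing `f_cross` (1/um), `resolution_um` and the SPS/NPS
#'   curves.
#' @export
estimate_resolution <- function(signal, background, n_planes = 256,
                                band = NULL) {
  vs <- signal$voxel_size_um
  nyq <- 1 / (2 * vs)
  if (is.null(band)) band <- c(0.05, nyq)
  res <- list()
  for (orient in c("xy", "xz")) {
    sp <- extract_planes(as_vol_array(signal), orient, n_planes)
    np <- extract_planes(as_vol_array(background), orient, n_planes)
    sps <- radial_power_spectrum(sp, vs)
    nps <- radial_power_spectrum(np, vs)
    freq <- sps$freq
    in_band <- freq >= band[1] & freq <= band[2] & sps$power > 0
    if (sum(in_band) < 4L) stop("too few spectral samples in the band")
    fit <- stats::lm(log10(power) ~ poly(freq, 2, raw = TRUE),
                     data = sps[in_band, ])
    sfit <- 10^stats::predict(fit, newdata = data.frame(freq = freq[in_band]))
    nband <- nps$power[in_band]
    gap <- sfit - 5 * nband
    idx <- which(gap <= 0)
    if (length(idx) == 0L)
      stop("no Rose-criterion crossing found in the sampled band (", orient, ")")
    i2 <- idx[1]
    fb <- freq[in_band]
    if (i2 == 1L) {
      fc <- fb[1]
    } else {
      i1 <- i2 - 1L
      w <- gap[i1] / (gap[i1] - gap[i2])
      fc <- fb[i1] + w * (fb[i2] - fb[i1])
    }
    res[[orient]] <- list(f_cross = fc,
                          resolution_um = half_period_resolution(fc),
                          freq = fb, sps = sfit, nps = nband)
  }
  res
}

extract_planes <- function(arr, orient, n_planes) {
  d <- dim(arr)
  if (orient == "xy") {
    n <- min(n_planes, d[1])
    lapply(round(seq(1, d[1], length.out = n)), function(i)
      array(arr[i, , ], dim = d[2:3]))
  } else {
    n <- min(n_planes, d[2])
    lapply(round(seq(1, d[2], length.out = n)), function(j)
      array(arr[, j, ], dim = d[c(1, 3)]))
  }
}
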