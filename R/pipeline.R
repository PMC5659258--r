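#' Run the full analysis pipeline from a configuration
#'
#' Executes classify -> detect/segment -> density/statistics on either a
#' synthetic phantom or a TIFF volume, writing all artifacts to
#' `config$out_dir`:
#'
#' * `cells.csv` - detected centroid table ([write_centroids()] format)
#' * `vessels.tif` - labeled vessel mask (16-bit multi-page TIFF)
#' * `density.csv` - per-bin density field (bin centers, `p`, `p_d`)
#' * `stats.csv` - cell-to-cell / cell-to-vessel distance summaries
#' * `manifest.json` - the resolved configuration and counters
#'
#' The run is deterministic given `config` (which includes the seed).
#'
#' @param config Path to a YAML file, or an equivalent nested list with
#'   entries: `seed`, `out_dir`; `phantom` (arguments for
#'   [phantom_spec()]) or `input` (`volume` TIFF path, `voxel_size_um`,
#'   and `model` path of a saved classifier); optional `classifier`
#'   (`scales_um`, `n_trees`, `n_per_class`), `detection`
#'   (`cell_size_vox`, `stop_threshold`, `max_iterations`,
#'   `block_shape`, `pad_vox`), `vessels` (`threshold`,
#'   `dilation_radius_vox`, `min_component_vox`), `density` (`k`,
#'   `bin_volume_um3`).
#' @return Invisibly, a list with the in-memory results (`detections`,
#'   `vessels`, `density`, `stats`, `paths`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config must give `out_dir`")
  if (is.null(config$seed)) stop("config must give `seed`")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)

  # ---- input volume ----
  if (!is.null(config$phantom)) {
    spec <- do.call(phantom_spec, c(config$phantom, list(seed = seed)))
    ph <- generate_phantom(spec)
    vol <- ph$intensity
  } else if (!is.null(config$input)) {
    ph <- NULL
    vol <- read_volume(config$input$volume,
                       voxel_size_um = config$input$voxel_size_um %||% 0.65)
  } else stop("config must give either `phantom` or `input`")

  # ---- probability maps ----
  ccfg <- config$classifier %||% list()
  if (!is.null(config$input$model)) {
    clf <- load_classifier(config$input$model)
  } else {
    if (is.null(ph)) stop("a classifier `model` is required for TIFF input")
    ann <- sample_annotations(ph, n_per_class = ccfg$n_per_class %||% 2000L,
                              seed = seed)
    feats <- compute_features(vol, scales_um = ccfg$scales_um %||%
                                c(0.65, 1.3, 2.6, 5.2))
    clf <- train_classifier(feats, ann, n_trees = ccfg$n_trees %||% 100L,
                            seed = seed)
    probs <- predict_probabilities(clf, feats)
  }
  if (!exists("probs", inherits = FALSE))
    probs <- predict_probabilities(clf, vol)

  # ---- detection ----
  dcfg <- config$detection %||% list()
  params <- detection_params(
    cell_size_vox = dcfg$cell_size_vox %||% 18L,
    stop_threshold = dcfg$stop_threshold %||% 0.47,
    max_iterations = dcfg$max_iterations %||% 10000L)
  if (!is.null(dcfg$block_shape)) {
    det <- detect_cells_blocked(probs, params,
                                block_shape = unlist(dcfg$block_shape),
                                pad_vox = dcfg$pad_vox %||% NULL)
  } else {
    det <- detect_cells(probs, params)
  }
  det <- estimate_cell_sizes(probs, det)

  # ---- vessels ----
  vcfg <- config$vessels %||% list()
  vessels <- segment_vessels(probs,
                             threshold = vcfg$threshold %||% 0.47,
                             dilation_radius_vox = vcfg$dilation_radius_vox %||% 2,
                             min_component_vox = vcfg$min_component_vox %||% 50)

  # ---- density and distance statistics ----
  kcfg <- config$density %||% list()
  dens <- if (nrow(det) > (kcfg$k %||% 5L))
    estimate_density(det, k = kcfg$k %||% 5L,
                     bin_volume_um3 = kcfg$bin_volume_um3 %||% 8.44)
  else NULL
  stats_df <- data.frame()
  if (nrow(det) >= 2L) {
    cc <- summarize_distances(cell_to_cell_distances(det))
    stats_df <- rbind(stats_df,
                      data.frame(statistic = "cell_to_cell_um",
                                 mean = cc$mean, sd = cc$sd, mode = cc$mode))
  }
  if (nrow(det) >= 1L && any(as_vol_array(vessels) > 0)) {
    cv <- summarize_distances(cell_to_vessel_distances(det, vessels))
    stats_df <- rbind(stats_df,
                      data.frame(statistic = "cell_to_vessel_um",
                                 mean = cv$mean, sd = cv$sd, mode = cv$mode))
  }

  # ---- artifacts ----
  paths <- list(cells = file.path(config$out_dir, "cells.csv"),
                vessels = file.path(config$out_dir, "vessels.tif"),
                density = file.path(config$out_dir, "density.csv"),
                stats = file.path(config$out_dir, "stats.csv"),
                manifest = file.path(config$out_dir, "manifest.json"))
  write_centroids(det, paths$cells)
  write_volume(vessels, paths$vessels)
  if (!is.null(dens)) {
    nb <- dim(dens$p)
    g <- expand.grid(x = seq_len(nb[1]), y = seq_len(nb[2]),
                     z = seq_len(nb[3]))
    utils::write.csv(
      data.frame(x_um = dens$origin_um[1] + (g$x - 0.5) * dens$bin_side_um,
                 y_um = dens$origin_um[2] + (g$y - 0.5) * dens$bin_side_um,
                 z_um = dens$origin_um[3] + (g$z - 0.5) * dens$bin_side_um,
                 p = as.numeric(dens$p), p_d = as.numeric(dens$p_d)),
      paths$density, row.names = FALSE)
  }
  utils::write.csv(stats_df, paths$stats, row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed,
         n_cells_detected = nrow(det),
         vascular_fraction_pct = vascular_fraction(vessels),
         config = config),
    paths$manifest, auto_unbox = TRUE, digits = NA)

  invisible(list(detections = det, vessels = vessels, density = dens,
                 stats = stats_df, paths = paths, phantom = ph))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
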