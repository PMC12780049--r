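#' Pipeline run configuration
#'
#' A declarative description of one co-registration run.  Values may come
#' from a YAML file ([read_run_config()]) with individual fields overridden
#' programmatically; unset fields take the documented defaults.
#'
#' @param visium_dir Space Ranger-style bundle directory.
#' @param msi_table MSI peak-by-pixel CSV/TSV.
#' @param output_dir Output directory (created).
#' @param landmarks Landmark CSV for direct registration
#'   (data-generated image frame -> Visium full-resolution frame).
#' @param landmarks_stage1,landmarks_stage2 Landmark CSVs for two-stage
#'   registration via an intermediate microscopy image; when both are set
#'   they take precedence over `landmarks`.
#' @param transform_kind `"affine"` or `"tps"`.
#' @param radius_mode `"expanded"`, `"visium"` or `"msi"`.
#' @param agg_fn `"sum"`, `"mean"` or `"weighted_average"`.
#' @param n_components Components of the data-generated image (1-3).
#' @param clip_percentiles Percentile clip for the image channels.
#' @param single_mz Optional m/z: use a single-peak image instead of PCA.
#' @param tic_normalize Apply TIC normalisation to the MSI table.
#' @param dedup_decimals Decimal places for peak deduplication (NULL skips).
#' @param min_peaks_per_pixel,min_total_intensity MSI pixel QC thresholds.
#' @param tissue_threshold PC1 tissue threshold (number or `"otsu"`).
#' @param pixel_pitch Optional MSI pitch in micrometres.
#' @param seed Integer seed recorded in the manifest and used for any
#'   stochastic step.
#' @return A validated `run_config` list.
#' @export
run_config <- function(visium_dir, msi_table, output_dir,
                       landmarks = NULL,
                       landmarks_stage1 = NULL, landmarks_stage2 = NULL,
                       transform_kind = c("affine", "tps"),
                       radius_mode = c("expanded", "visium", "msi"),
                       agg_fn = c("sum", "mean", "weighted_average"),
                       n_components = 3, clip_percentiles = c(1, 99),
                       single_mz = NULL,
                       tic_normalize = FALSE, dedup_decimals = NULL,
                       min_peaks_per_pixel = 0, min_total_intensity = 0,
                       tissue_threshold = "otsu",
                       pixel_pitch = NULL, seed = 1) {
  cfg <- list(
    visium_dir = visium_dir, msi_table = msi_table, output_dir = output_dir,
    landmarks = landmarks, landmarks_stage1 = landmarks_stage1,
    landmarks_stage2 = landmarks_stage2,
    transform_kind = match.arg(transform_kind),
    radius_mode = match.arg(radius_mode),
    agg_fn = match.arg(agg_fn),
    n_components = n_components, clip_percentiles = clip_percentiles,
    single_mz = single_mz, tic_normalize = tic_normalize,
    dedup_decimals = dedup_decimals,
    min_peaks_per_pixel = min_peaks_per_pixel,
    min_total_intensity = min_total_intensity,
    tissue_threshold = tissue_threshold,
    pixel_pitch = pixel_pitch, seed = as.integer(seed)
  )
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  fail <- function(msg) abort(msg, class = "msialign_config_error")
  for (f in c("visium_dir", "msi_table")) {
    if (is.null(cfg[[f]])) fail(sprintf("config field '%s' is required", f))
    if (!file.exists(cfg[[f]])) fail(sprintf("config path %s = '%s' does not exist", f, cfg[[f]]))
  }
  two_stage <- !is.null(cfg$landmarks_stage1) || !is.null(cfg$landmarks_stage2)
  if (two_stage && (is.null(cfg$landmarks_stage1) || is.null(cfg$landmarks_stage2))) {
    fail("two-stage registration needs both landmarks_stage1 and landmarks_stage2")
  }
  if (!two_stage && is.null(cfg$landmarks)) fail("a landmark file is required")
  for (f in c("landmarks", "landmarks_stage1", "landmarks_stage2")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      fail(sprintf("config path %s = '%s' does not exist", f, cfg[[f]]))
    }
  }
  if (!cfg$transform_kind %in% c("affine", "tps")) fail("invalid transform_kind")
  if (!cfg$radius_mode %in% c("expanded", "visium", "msi")) fail("invalid radius_mode")
  if (!cfg$agg_fn %in% c("sum", "mean", "weighted_average")) fail("invalid agg_fn")
  if (!cfg$n_components %in% 1:3) fail("n_components must be 1, 2 or 3")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @param ... Overrides applied on top of the file values.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path),
                                class = "msialign_config_error")
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "msialign_stage_error")) stop(e)
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
          class = "msialign_stage_error")
  })
}

#' Run the full co-registration pipeline
#'
#' Executes read -> MSI preprocessing -> data-generated image ->
#' registration (one- or two-stage, depending on the landmark files given)
#' -> coordinate + image transformation -> pixel-to-spot aggregation ->
#' Space Ranger-style output.  The output directory receives the aligned
#' MSI bundle, the mapping CSV, the fitted transform JSON, the
#' data-generated image with its frame sidecar, an alignment report JSON,
#' and a run manifest recording every decision value, so a run is
#' auditable and re-running the same config is bit-identical.
#'
#' @param config A [run_config()] (or a YAML path).
#' @return Invisibly, a list with the `alignment_report`, the
#'   `multimodal_matrix` and the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- validate_run_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)

  visium <- stage("read_visium", read_spaceranger(cfg$visium_dir))
  msi <- stage("read_msi", read_peak_table(cfg$msi_table, pixel_pitch = cfg$pixel_pitch))
  msi <- stage("preprocess_msi", {
    if (isTRUE(cfg$tic_normalize)) msi <- tic_normalize(msi)
    if (!is.null(cfg$dedup_decimals)) msi <- deduplicate_peaks(msi, cfg$dedup_decimals)
    if (cfg$min_peaks_per_pixel > 0 || cfg$min_total_intensity > 0) {
      msi <- filter_msi(msi, cfg$min_peaks_per_pixel, cfg$min_total_intensity)
    }
    msi
  })

  img <- stage("image", {
    if (!is.null(cfg$single_mz)) single_peak_image(msi, cfg$single_mz)
    else pca_rgb_image(msi, cfg$n_components, cfg$clip_percentiles)
  })
  img_path <- file.path(cfg$output_dir, "msi_data_image.png")
  write_msi_image(img, img_path)

  transform <- stage("register", {
    if (!is.null(cfg$landmarks_stage1)) {
      t1 <- estimate_transform(read_landmarks(cfg$landmarks_stage1), cfg$transform_kind)
      t2 <- estimate_transform(read_landmarks(cfg$landmarks_stage2), cfg$transform_kind)
      compose_transforms(t2, t1)
    } else {
      estimate_transform(read_landmarks(cfg$landmarks), cfg$transform_kind)
    }
  })
  write_transform(transform, file.path(cfg$output_dir, "transform.json"))

  coords <- stage("apply", apply_transform(transform, as.matrix(msi$pixels[, c("x", "y")])))

  warped_image <- stage("transform_image", {
    sf <- visium$scalefactors
    if (!is.null(visium$images$hires)) {
      # raster (x=col, y=row, 0-based) -> MSI native -> fullres -> hires px
      fr <- img$frame
      raster_to_native_t <- new_spatial_transform("affine", matrix = rbind(
        c(fr$xstep, 0, fr$x0), c(0, fr$ystep, fr$y0), c(0, 0, 1)))
      to_hires <- new_spatial_transform("affine", matrix = diag(c(
        sf$tissue_hires_scalef, sf$tissue_hires_scalef, 1)))
      chain <- compose_transforms(to_hires, compose_transforms(transform, raster_to_native_t))
      transform_image(img, chain, dim(visium$images$hires)[1:2])$raster
    } else NULL
  })

  mapping <- stage("aggregate", {
    radius <- compute_spot_radius(visium, msi, cfg$radius_mode)
    map_pixels_to_spots(visium, coords, radius, cfg$radius_mode,
                        pixel_ids = msi$pixels$pixel_id)
  })
  mm <- aggregate_pixels(mapping, msi, cfg$agg_fn)

  report <- stage("evaluate", {
    pixel_labels <- tissue_labels_from_pc1(msi, cfg$tissue_threshold)
    spot_labels <- spot_labels_from_pixels(mapping, pixel_labels,
                                           pixel_ids = msi$pixels$pixel_id)
    alignment_accuracy(visium_tissue_labels(visium), spot_labels,
                       settings = list(kind = cfg$transform_kind,
                                       stage = if (!is.null(cfg$landmarks_stage1))
                                         "intermediate" else "direct",
                                       seed = cfg$seed))
  })

  bundle_dir <- file.path(cfg$output_dir, "aligned_msi")
  stage("write", {
    write_multimodal_bundle(mm, visium, bundle_dir,
                            image = if (!is.null(warped_image))
                              pmin(pmax(warped_image, 0), 255) else NULL)
    write_mapping(mapping, file.path(cfg$output_dir, "mapping.csv"))
    jsonlite::write_json(
      list(accuracy = report$accuracy, n_spots = report$n_spots,
           counts = as.list(report$counts), settings = report$settings),
      file.path(cfg$output_dir, "alignment_report.json"),
      auto_unbox = TRUE, digits = I(17))
  })

  manifest <- list(
    config = unclass(cfg),
    decisions = list(
      weight_epsilon = 1e-6 * mapping$radius,
      pca_unit_variance_scaling = FALSE,
      pca_sign_rule = "largest-|loading| positive",
      pixel_tie_rule = "nearest spot, ties to lexicographically smallest barcode",
      spot_label_rule = "majority vote over assigned pixels, ties to tissue",
      empty_spot_rule = "zero row, flagged",
      tissue_threshold = cfg$tissue_threshold,
      radius_fullres_px = mapping$radius,
      unassigned_pixels = length(mapping$unassigned)
    )
  )
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null")

  invisible(list(report = report, matrix = mm, mapping = mapping,
                 transform = transform,
                 paths = list(bundle = bundle_dir, output = cfg$output_dir)))
}
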