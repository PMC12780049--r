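#' Synthetic paired Visium + MSI scenarios with known ground truth
#'
#' The generator emulates the geometry of a paired acquisition on
#' consecutive sections: a hexagonal Visium spot lattice over a tissue mask
#' (an ellipse with two interior holes, giving the boundary features that
#' make landmarking workable), and a rectilinear MSI pixel raster related
#' to the Visium full-resolution frame by a known, invertible warp.  Peak
#' intensities are spatially correlated with the tissue mask, with one
#' structural peak tracking the mask, one compound peak confined to
#' hotspot discs, and uninformative noise peaks.  Everything is
#' byte-reproducible from the stored seed.
#'
#' @param seed Integer seed stored on the truth object.
#' @param warp A `spatial_transform` mapping MSI native coordinates into
#'   the Visium full-resolution frame.  Default: an 8-degree rotation plus
#'   a (350, 260) px translation — a displacement of several spot spacings,
#'   so an unregistered overlay is visibly wrong.
#' @param mask_params Ellipse-with-holes parameters in the full-resolution
#'   frame: `cx`, `cy`, `a`, `b`, and `holes` (list of `c(x, y, r)`).
#' @param hotspots Compound deposition discs, list of `c(x, y, r)` in the
#'   full-resolution frame.
#' @param intensity_model Per-peak tibble: `mz`, `baseline`,
#'   `tissue_effect`, `noise_sd`, `hotspot` (logical).
#' @return A `synthetic_truth` object.
#' @export
synthetic_truth <- function(seed = 1,
                            warp = NULL,
                            mask_params = list(cx = 700, cy = 560, a = 500, b = 380,
                                               holes = list(c(500, 400, 80),
                                                            c(900, 700, 60))),
                            hotspots = list(c(600, 650, 110), c(850, 450, 80)),
                            intensity_model = NULL) {
  if (is.null(warp)) {
    th <- 8 * pi / 180
    m <- rbind(c(cos(th), -sin(th), 350),
               c(sin(th), cos(th), 260),
               c(0, 0, 1))
    warp <- new_spatial_transform("affine", matrix = m,
                                  domain_frame = "msi_native",
                                  codomain_frame = "fullres")
  }
  if (is.null(intensity_model)) {
    intensity_model <- tibble(
      mz = c(89.02435, 218.10372, 550.15724, 100.10, 150.20),
      baseline = c(40, 30, 0, 20, 15),
      tissue_effect = c(160, 90, 0, 0, 0),
      noise_sd = c(8, 6, 0, 4, 3),
      hotspot = c(FALSE, FALSE, TRUE, FALSE, FALSE)
    )
  }
  structure(
    list(warp = warp, mask_params = mask_params, hotspots = hotspots,
         intensity_model = intensity_model, rng_seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth: seed %d, %s warp, %d peaks>\n",
              x$rng_seed, x$warp$kind, nrow(x$intensity_model)))
  invisible(x)
}

#' Evaluate the ground-truth tissue mask
#' @param truth A [synthetic_truth()].
#' @param x,y Coordinates in the Visium full-resolution frame.
#' @return Logical vector: inside the tissue mask.
#' @export
truth_mask <- function(truth, x, y) {
  p <- truth$mask_params
  inside <- ((x - p$cx) / p$a)^2 + ((y - p$cy) / p$b)^2 <= 1
  for (h in p$holes) inside <- inside & ((x - h[1])^2 + (y - h[2])^2 > h[3]^2)
  inside
}

in_hotspot <- function(truth, x, y) {
  hit <- rep(FALSE, length(x))
  for (h in truth$hotspots) hit <- hit | ((x - h[1])^2 + (y - h[2])^2 <= h[3]^2)
  hit
}

#' Simulate a Visium dataset on a hexagonal lattice
#'
#' Spots sit on a hexagonal array: odd array rows are offset by half the
#' spacing and the row pitch is `spacing_px * sqrt(3) / 2`, so the minimum
#' centre distance equals `spacing_px`.  `in_tissue` comes from the truth
#' mask; a small gene panel is drawn from a negative-binomial model
#' (dispersion 0.5) whose mean is elevated inside the mask for the first
#' third of genes.  The panel includes ribosomal/mitochondrial-style names
#' so gene-pattern filters are exercisable.
#'
#' @param truth A [synthetic_truth()].
#' @param n_rows,n_cols Array dimensions (>= 2).
#' @param spacing_px Centre-to-centre spacing in full-resolution pixels.
#' @param n_genes Gene panel size.
#' @param mu_background,mu_tissue NB means outside/inside the mask for the
#'   tissue-elevated genes.
#' @param hires_scalef Scale factor of the rendered hires mask image.
#' @return A [visium_dataset()].
#' @export
simulate_visium <- function(truth, n_rows = 14, n_cols = 14, spacing_px = 100,
                            n_genes = 30, mu_background = 2, mu_tissue = 20,
                            hires_scalef = 0.1) {
  stopifnot(n_rows >= 2, n_cols >= 2, spacing_px > 0)
  grid <- tidyr::expand_grid(array_row = 0:(n_rows - 1), array_col = 0:(n_cols - 1))
  x <- grid$array_col * spacing_px + (grid$array_row %% 2) * spacing_px / 2
  y <- grid$array_row * spacing_px * sqrt(3) / 2
  barcodes <- sprintf("SP%03d_%03d-1", grid$array_row, grid$array_col)
  tissue <- truth_mask(truth, x, y)

  gene_names <- c(sprintf("Gene%02d", seq_len(max(0, n_genes - 5))),
                  c("Rpl3", "Rps6", "Mrpl15", "mt-Co1", "mt-Nd1"))[seq_len(n_genes)]
  elevated <- seq_len(ceiling(n_genes / 3))
  counts <- withr::with_seed(truth$rng_seed, {
    mat <- matrix(0L, n_genes, length(barcodes))
    for (g in seq_len(n_genes)) {
      mu <- if (g %in% elevated) ifelse(tissue, mu_tissue, mu_background)
            else rep(mu_background, length(tissue))
      mat[g, ] <- rnbinom(length(mu), mu = mu, size = 2)  # dispersion 0.5
    }
    mat
  })
  rownames(counts) <- gene_names

  sf <- list(spot_diameter_fullres = 0.55 * spacing_px,
             tissue_hires_scalef = hires_scalef,
             tissue_lowres_scalef = hires_scalef * 0.3)
  W <- ceiling((max(x) + spacing_px) * hires_scalef)
  H <- ceiling((max(y) + spacing_px) * hires_scalef)
  ix <- rep(seq_len(W), each = H); iy <- rep(seq_len(H), times = W)
  img <- matrix(ifelse(truth_mask(truth, (ix - 0.5) / hires_scalef,
                                  (iy - 0.5) / hires_scalef), 0.55, 0.95), H, W)

  visium_dataset(
    barcodes = barcodes,
    features = tibble(id = gene_names, name = gene_names,
                      feature_type = "Gene Expression"),
    counts = Matrix::Matrix(counts, sparse = TRUE),
    positions = tibble(barcode = barcodes, in_tissue = as.integer(tissue),
                       array_row = grid$array_row, array_col = grid$array_col,
                       pxl_row_in_fullres = y, pxl_col_in_fullres = x),
    scalefactors = sf,
    images = list(hires = img)
  )
}

#' Simulate an MSI dataset warped away from a Visium fixture
#'
#' Lays a rectilinear pixel grid over the inverse-warped Visium extent so
#' that, once registered with the true warp, the pixels cover the spot
#' array.  Intensities follow the truth's per-peak model: `baseline +
#' tissue_effect * mask(warp(pixel)) + N(0, noise_sd)` truncated at zero;
#' hotspot peaks are nonzero only inside the deposition discs.
#'
#' @param truth A [synthetic_truth()].
#' @param visium The [visium_dataset()] defining the target extent.
#' @param resolution_factor Pixels per spot spacing (grid step =
#'   spacing / resolution_factor); 3 mimics a 65 um raster against 100 um
#'   spot pitch.
#' @param hotspot_intensity Intensity of the compound peak inside hotspots.
#' @param pixel_pitch Micrometre pitch stored on the dataset (default 65).
#' @return An [msi_dataset()] in MSI native coordinates.
#' @export
simulate_msi <- function(truth, visium, resolution_factor = 3,
                         hotspot_intensity = 200, pixel_pitch = 65) {
  stopifnot(resolution_factor > 0)
  ctr <- spot_centers(visium)
  pad <- visium$scalefactors$spot_diameter_fullres
  corners <- as.matrix(tidyr::expand_grid(
    x = range(ctr$x) + c(-pad, pad), y = range(ctr$y) + c(-pad, pad)))
  native <- apply_transform(invert_transform(truth$warp), corners)
  spacing <- compute_spot_radius(visium, mode = "expanded") * 2
  step <- spacing / resolution_factor
  gx <- seq(min(native[, 1]), max(native[, 1]), by = step)
  gy <- seq(min(native[, 2]), max(native[, 2]), by = step)
  grid <- as.matrix(tidyr::expand_grid(x = gx, y = gy))

  full <- apply_transform(truth$warp, grid)
  tissue <- truth_mask(truth, full[, 1], full[, 2])
  hot <- in_hotspot(truth, full[, 1], full[, 2])

  im <- truth$intensity_model
  ints <- withr::with_seed(truth$rng_seed + 1L, {
    m <- matrix(0, nrow(grid), nrow(im))
    for (j in seq_len(nrow(im))) {
      if (im$hotspot[j]) {
        v <- ifelse(hot, hotspot_intensity, 0)
        if (im$noise_sd[j] > 0) v <- v + ifelse(hot, rnorm(length(hot), 0, im$noise_sd[j]), 0)
      } else {
        v <- im$baseline[j] + im$tissue_effect[j] * tissue +
          rnorm(length(tissue), 0, im$noise_sd[j])
      }
      m[, j] <- pmax(v, 0)
    }
    m
  })

  msi_dataset(
    pixels = tibble(pixel_id = sprintf("px%06d", seq_len(nrow(grid))),
                    x = grid[, 1], y = grid[, 2],
                    true_label = ifelse(tissue, "tissue", "background")),
    mz = im$mz, intensities = ints, pixel_pitch = pixel_pitch
  )
}

#' Sample a landmark pool from the ground-truth warp
#'
#' Draws `n` points along the tissue-mask boundary region (where a human
#' would pick landmarks), takes their MSI-native positions through the
#' inverse warp as sources, and sets targets to `warp(source)` plus
#' optional Gaussian jitter.  With `jitter_sd = 0` the pool satisfies the
#' warp exactly, so transform-recovery tests are exact.
#'
#' @param truth A [synthetic_truth()].
#' @param n Number of landmark pairs (>= 3).
#' @param jitter_sd Gaussian jitter (full-resolution px) on the targets.
#' @param seed Seed for sampling and jitter.
#' @param intermediate_warp Optional `spatial_transform` (native -> an
#'   intermediate microscopy frame); adds exact `micro_x`/`micro_y`
#'   columns for two-stage registration tests.
#' @return Landmark tibble (`stage`, `source_x`, `source_y`, `target_x`,
#'   `target_y`, and micro columns when requested).
#' @export
simulate_landmarks <- function(truth, n = 20, jitter_sd = 0, seed = truth$rng_seed,
                               intermediate_warp = NULL) {
  if (n < 3) abort("at least 3 landmark pairs are required")
  p <- truth$mask_params
  pts <- withr::with_seed(seed, {
    th <- runif(n, 0, 2 * pi)
    r <- runif(n, 0.55, 1.05)       # boundary band of the ellipse
    cbind(x = p$cx + r * p$a * cos(th), y = p$cy + r * p$b * sin(th))
  })
  src <- apply_transform(invert_transform(truth$warp), pts)
  tgt <- apply_transform(truth$warp, src)
  if (jitter_sd > 0) {
    tgt <- tgt + withr::with_seed(seed + 7L, matrix(rnorm(2 * n, 0, jitter_sd), n, 2))
  }
  out <- tibble(stage = "msi_data-visium",
                source_x = src[, 1], source_y = src[, 2],
                target_x = tgt[, 1], target_y = tgt[, 2])
  if (!is.null(intermediate_warp)) {
    mic <- apply_transform(intermediate_warp, src)
    out$micro_x <- mic[, 1]
    out$micro_y <- mic[, 2]
  }
  out
}

#' Write a complete synthetic scenario to disk
#'
#' Emits a Space Ranger-style Visium bundle, an MSI peak-table CSV, a
#' landmark CSV, and a truth JSON (warp + mask parameters + seed), giving
#' an end-to-end test input with known geometry.
#'
#' @param dir Output directory (created).
#' @param seed Scenario seed.
#' @param n_landmarks Pool size written to `landmarks.csv`.
#' @param jitter_sd Landmark jitter in full-resolution px.
#' @param ... Passed to [simulate_visium()].
#' @return Invisibly, a list with the objects and file paths.
#' @export
simulate_scenario <- function(dir, seed = 1, n_landmarks = 20, jitter_sd = 0, ...) {
  truth <- synthetic_truth(seed = seed)
  visium <- simulate_visium(truth, ...)
  msi <- simulate_msi(truth, visium)
  landmarks <- simulate_landmarks(truth, n = n_landmarks, jitter_sd = jitter_sd)

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vis_dir <- file.path(dir, "visium")
  write_spaceranger_style(visium$counts, visium$positions, visium$scalefactors,
                          vis_dir, features = visium$features,
                          barcodes = visium$barcodes, image = visium$images$hires)
  msi_path <- file.path(dir, "msi_peaks.csv")
  write_peak_table(msi, msi_path)
  lm_path <- file.path(dir, "landmarks.csv")
  write_landmarks(landmarks, lm_path)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(rng_seed = truth$rng_seed, mask_params = truth$mask_params,
         hotspots = truth$hotspots, warp_matrix = truth$warp$matrix,
         intensity_model = truth$intensity_model),
    truth_path, auto_unbox = TRUE, digits = I(17))

  invisible(list(truth = truth, visium = visium, msi = msi, landmarks = landmarks,
                 paths = list(visium = vis_dir, msi = msi_path,
                              landmarks = lm_path, truth = truth_path)))
}
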