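# Small fixtures shared across test files.  Heavier synthetic scenarios are
# built once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# default synthetic scenario (hex Visium + warped MSI + exact landmark pool)
get_scenario <- function(seed = 1, resolution_factor = 3) {
  cached(sprintf("scen_%d_%d", seed, resolution_factor), function() {
    truth <- synthetic_truth(seed = seed)
    visium <- simulate_visium(truth)
    msi <- simulate_msi(truth, visium, resolution_factor = resolution_factor)
    list(truth = truth, visium = visium, msi = msi,
         landmarks = simulate_landmarks(truth, n = 20, seed = seed))
  })
}

# tiny MSI dataset on a rectilinear grid with hand-set intensities
make_toy_msi <- function(intensities, coords = NULL, mz = NULL) {
  n <- nrow(intensities)
  if (is.null(coords)) {
    side <- ceiling(sqrt(n))
    coords <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side)))[seq_len(n), , drop = FALSE]
  }
  if (is.null(mz)) mz <- 100 + seq_len(ncol(intensities))
  msi_dataset(
    tibble::tibble(pixel_id = sprintf("px%03d", seq_len(n)),
                   x = coords[, 1], y = coords[, 2]),
    mz = mz, intensities = intensities
  )
}

# tiny Visium dataset with explicit spot centres (x, y in fullres px)
make_toy_visium <- function(centers, counts = NULL, gene_names = NULL,
                            in_tissue = NULL, spot_diameter = 90) {
  n <- nrow(centers)
  barcodes <- sprintf("BC%03d-1", seq_len(n))
  if (is.null(counts)) counts <- matrix(1, 2, n, dimnames = list(c("GeneA", "GeneB"), barcodes))
  if (is.null(gene_names)) gene_names <- rownames(counts)
  if (is.null(in_tissue)) in_tissue <- rep(1L, n)
  visium_dataset(
    barcodes = barcodes,
    features = tibble::tibble(id = gene_names, name = gene_names,
                              feature_type = "Gene Expression"),
    counts = Matrix::Matrix(counts, sparse = TRUE),
    positions = tibble::tibble(barcode = barcodes, in_tissue = as.integer(in_tissue),
                               array_row = seq_len(n) - 1L, array_col = seq_len(n) - 1L,
                               pxl_row_in_fullres = centers[, 2],
                               pxl_col_in_fullres = centers[, 1]),
    scalefactors = list(spot_diameter_fullres = spot_diameter,
                        tissue_hires_scalef = 0.1, tissue_lowres_scalef = 0.03)
  )
}

random_affine <- function(seed, scale_range = c(0.8, 1.2)) {
  withr::with_seed(seed, {
    th <- runif(1, -pi / 4, pi / 4)
    s <- runif(2, scale_range[1], scale_range[2])
    sh <- runif(1, -0.2, 0.2)
    t <- runif(2, -50, 50)
    A <- rbind(c(s[1] * cos(th), -s[1] * sin(th) + sh, t[1]),
               c(s[2] * sin(th), s[2] * cos(th), t[2]),
               c(0, 0, 1))
    msialign:::new_spatial_transform("affine", matrix = A)
  })
}
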