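#' Visium Space Ranger bundles
#'
#' A `visium_dataset` holds a Space Ranger-style Visium bundle: the sparse
#' feature-barcode count matrix, per-spot array and full-resolution pixel
#' positions, the scale factors relating full-resolution pixels to the
#' hires/lowres images, and the images themselves when present.
#'
#' @param barcodes Character vector of spot barcodes (matrix column order).
#' @param features Tibble with columns `id`, `name`, `feature_type`.
#' @param counts `Matrix::dgCMatrix`, features x barcodes, non-negative.
#' @param positions Tibble with columns `barcode`, `in_tissue`, `array_row`,
#'   `array_col`, `pxl_row_in_fullres`, `pxl_col_in_fullres`.
#' @param scalefactors Named list with at least `spot_diameter_fullres`,
#'   `tissue_hires_scalef`, `tissue_lowres_scalef`.
#' @param images Named list of rasters (`hires`, `lowres`), may be empty.
#' @return A `visium_dataset`.
#' @export
visium_dataset <- function(barcodes, features, counts, positions, scalefactors,
                           images = list()) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  features <- as_tibble(features)
  positions <- as_tibble(positions)
  stopifnot(all(c("id", "name", "feature_type") %in% names(features)),
            all(c("barcode", "in_tissue", "array_row", "array_col",
                  "pxl_row_in_fullres", "pxl_col_in_fullres") %in% names(positions)))
  if (length(barcodes) != ncol(counts)) abort("one barcode per counts column required")
  if (nrow(features) != nrow(counts)) abort("one feature per counts row required")
  if (any(counts@x < 0)) abort("counts must be non-negative")
  if (!all(barcodes %in% positions$barcode)) {
    abort("every barcode in the matrix needs a position record")
  }
  positions <- positions[match(barcodes, positions$barcode), ]
  sf <- scalefactors
  for (k in c("spot_diameter_fullres", "tissue_hires_scalef", "tissue_lowres_scalef")) {
    if (is.null(sf[[k]])) stopf("scalefactors missing '%s'", k)
  }
  if (sf$spot_diameter_fullres <= 0) abort("spot_diameter_fullres must be > 0")
  if (sf$tissue_hires_scalef <= 0 || sf$tissue_hires_scalef > 1) {
    abort("tissue_hires_scalef must be in (0, 1]")
  }
  if (any(positions$array_row < 0) || any(positions$array_col < 0)) {
    abort("array_row/array_col must be non-negative")
  }
  dimnames(counts) <- NULL
  structure(
    list(barcodes = as.character(barcodes), features = features, counts = counts,
         positions = positions, scalefactors = sf, images = images),
    class = "visium_dataset"
  )
}

#' @export
print.visium_dataset <- function(x, ...) {
  cat(sprintf("<visium_dataset: %d features x %d spots (%d in tissue)>\n",
              nrow(x$counts), ncol(x$counts), sum(x$positions$in_tissue)))
  invisible(x)
}

#' @export
dim.visium_dataset <- function(x) dim(x$counts)

#' Spot centres in full-resolution pixel (x, y) coordinates
#'
#' `tissue_positions` stores (row, col); geometry code works in (x, y) with
#' x = column direction.  This accessor does the swap once.
#'
#' @param ds A [visium_dataset()].
#' @return Tibble with `barcode`, `x`, `y`, `in_tissue`.
#' @export
spot_centers <- function(ds) {
  stopifnot(inherits(ds, "visium_dataset"))
  tibble(barcode = ds$positions$barcode,
         x = ds$positions$pxl_col_in_fullres,
         y = ds$positions$pxl_row_in_fullres,
         in_tissue = ds$positions$in_tissue)
}

POSITION_COLS <- c("barcode", "in_tissue", "array_row", "array_col",
                   "pxl_row_in_fullres", "pxl_col_in_fullres")

read_tissue_positions <- function(spatial_dir) {
  v2 <- file.path(spatial_dir, "tissue_positions.csv")
  v1 <- file.path(spatial_dir, "tissue_positions_list.csv")
  if (file.exists(v2)) {
    pos <- readr::read_csv(v2, show_col_types = FALSE, progress = FALSE)
    if (!all(POSITION_COLS %in% names(pos))) {
      stopf("tissue_positions.csv lacks the expected columns (%s)",
            paste(setdiff(POSITION_COLS, names(pos)), collapse = ", "))
    }
  } else if (file.exists(v1)) {
    pos <- readr::read_csv(v1, col_names = POSITION_COLS,
                           show_col_types = FALSE, progress = FALSE)
  } else {
    stopf("no tissue positions table (tissue_positions.csv or tissue_positions_list.csv) in %s",
          spatial_dir)
  }
  pos <- as_tibble(pos)[, POSITION_COLS]
  pos$barcode <- as.character(pos$barcode)
  pos$in_tissue <- as.integer(pos$in_tissue)
  pos$array_row <- as.integer(pos$array_row)
  pos$array_col <- as.integer(pos$array_col)
  pos$pxl_row_in_fullres <- as.numeric(pos$pxl_row_in_fullres)
  pos$pxl_col_in_fullres <- as.numeric(pos$pxl_col_in_fullres)
  pos
}

read_10x_h5 <- function(h5) {
  on.exit(rhdf5::H5close(), add = TRUE)
  shape <- as.integer(rhdf5::h5read(h5, "matrix/shape"))
  counts <- Matrix::sparseMatrix(
    i = as.integer(rhdf5::h5read(h5, "matrix/indices")) + 1L,
    p = as.integer(rhdf5::h5read(h5, "matrix/indptr")),
    x = as.numeric(rhdf5::h5read(h5, "matrix/data")),
    dims = shape
  )
  list(
    counts = counts,
    barcodes = as.character(rhdf5::h5read(h5, "matrix/barcodes")),
    features = tibble(
      id = as.character(rhdf5::h5read(h5, "matrix/features/id")),
      name = as.character(rhdf5::h5read(h5, "matrix/features/name")),
      feature_type = as.character(rhdf5::h5read(h5, "matrix/features/feature_type"))
    )
  )
}

#' Read a Space Ranger-style Visium bundle
#'
#' Expects `filtered_feature_bc_matrix.h5` (10x HDF5 feature-barcode
#' schema), a `spatial/` folder with a tissue positions table (both the
#' Space Ranger v1 headerless `tissue_positions_list.csv` and the v2
#' headered `tissue_positions.csv` dialects are accepted) and
#' `scalefactors_json.json`; hires/lowres PNGs are optional.  Spots present
#' in the positions table but absent from the matrix are dropped with a
#' message; a barcode overlap below 50% is treated as a wrong-bundle signal
#' and is fatal.
#'
#' @param path Bundle directory.
#' @return A [visium_dataset()].
#' @export
read_spaceranger <- function(path) {
  if (!dir.exists(path)) stopf("bundle directory not found: %s", path)
  h5 <- file.path(path, "filtered_feature_bc_matrix.h5")
  if (!file.exists(h5)) stopf("missing required file: filtered_feature_bc_matrix.h5 in %s", path)
  spatial <- file.path(path, "spatial")
  sf_path <- file.path(spatial, "scalefactors_json.json")
  if (!file.exists(sf_path)) stopf("missing required file: scalefactors_json.json in %s", spatial)

  mat <- read_10x_h5(h5)
  pos <- read_tissue_positions(spatial)
  sf <- tryCatch(jsonlite::read_json(sf_path, simplifyVector = TRUE),
                 error = function(e) stopf("malformed scalefactors_json.json: %s", conditionMessage(e)))
  for (k in c("spot_diameter_fullres", "tissue_hires_scalef", "tissue_lowres_scalef",
              "fiducial_diameter_fullres")) {
    if (!is.null(sf[[k]])) sf[[k]] <- as.numeric(sf[[k]])
  }

  overlap <- mean(mat$barcodes %in% pos$barcode)
  if (overlap < 0.5) {
    stopf("only %.0f%% of matrix barcodes have positions: wrong bundle?", 100 * overlap)
  }
  keep <- mat$barcodes %in% pos$barcode
  if (!all(keep)) {
    inform(sprintf("read_spaceranger: dropped %d matrix barcode(s) without positions", sum(!keep)))
  }
  dropped_pos <- sum(!pos$barcode %in% mat$barcodes)
  if (dropped_pos > 0) {
    inform(sprintf("read_spaceranger: %d position record(s) absent from the matrix dropped", dropped_pos))
  }

  images <- list()
  for (nm in c("hires", "lowres")) {
    p <- file.path(spatial, sprintf("tissue_%s_image.png", nm))
    if (file.exists(p)) images[[nm]] <- png::readPNG(p)
  }

  visium_dataset(mat$barcodes[keep], mat$features, mat$counts[, keep, drop = FALSE],
                 pos[pos$barcode %in% mat$barcodes, ], as.list(sf), images)
}

#' Write a Space Ranger-style bundle
#'
#' Emits `filtered_feature_bc_matrix.h5` in the 10x compressed-sparse
#' feature-barcode schema plus a `spatial/` folder with the headered
#' tissue positions table, scale factors JSON, and the image (if given).
#' The bundle is re-readable by [read_spaceranger()] and by standard
#' community Visium loaders.  Matrix values are stored as floating point,
#' preserving continuous (e.g. TIC-normalised) intensities exactly.
#'
#' @param matrix Feature x barcode matrix (dense or `dgCMatrix`), finite,
#'   non-negative; `dimnames` give feature names and barcodes unless
#'   `features`/`barcodes` are supplied.
#' @param positions Tibble of position records as in [visium_dataset()].
#' @param scalefactors Named list of scale factors.
#' @param path Output directory (created).
#' @param features Optional features tibble (`id`, `name`, `feature_type`).
#' @param barcodes Optional barcode vector (defaults to `colnames(matrix)`).
#' @param image Optional hires raster (numeric array in [0, 1] or [0, 255]).
#' @param feature_type Default feature type when `features` is not given.
#' @return The bundle directory, invisibly.
#' @export
write_spaceranger_style <- function(matrix, positions, scalefactors, path,
                                    features = NULL, barcodes = NULL,
                                    image = NULL, feature_type = "Gene Expression") {
  m <- methods::as(methods::as(Matrix::Matrix(matrix, sparse = TRUE), "CsparseMatrix"),
                   "generalMatrix")
  if (any(!is.finite(m@x))) abort("non-finite values in matrix")
  if (is.null(barcodes)) barcodes <- colnames(m)
  if (is.null(barcodes)) abort("barcodes must be supplied (argument or colnames)")
  positions <- as_tibble(positions)
  if (ncol(m) != nrow(positions)) {
    stopf("matrix has %d columns but %d position records given", ncol(m), nrow(positions))
  }
  if (is.null(features)) {
    ids <- rownames(m) %||% sprintf("feature%05d", seq_len(nrow(m)))
    features <- tibble(id = ids, name = ids, feature_type = feature_type)
  }

  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  spatial <- file.path(path, "spatial")
  dir.create(spatial, showWarnings = FALSE)
  if (!dir.exists(spatial)) stopf("cannot create output directory %s", spatial)

  h5 <- file.path(path, "filtered_feature_bc_matrix.h5")
  if (file.exists(h5)) file.remove(h5)
  rhdf5::h5createFile(h5)
  rhdf5::h5createGroup(h5, "matrix")
  rhdf5::h5createGroup(h5, "matrix/features")
  rhdf5::h5write(m@x, h5, "matrix/data")
  rhdf5::h5write(m@i, h5, "matrix/indices")
  rhdf5::h5write(m@p, h5, "matrix/indptr")
  rhdf5::h5write(dim(m), h5, "matrix/shape")
  rhdf5::h5write(as.character(barcodes), h5, "matrix/barcodes")
  rhdf5::h5write(as.character(features$id), h5, "matrix/features/id")
  rhdf5::h5write(as.character(features$name), h5, "matrix/features/name")
  rhdf5::h5write(as.character(features$feature_type), h5, "matrix/features/feature_type")
  rhdf5::h5write(rep("unknown", nrow(features)), h5, "matrix/features/genome")
  fid <- rhdf5::H5Fopen(h5)
  rhdf5::h5writeAttribute(basename(path), fid, "library_ids")
  rhdf5::H5Fclose(fid)
  rhdf5::H5close()

  readr::write_csv(positions[, POSITION_COLS], file.path(spatial, "tissue_positions.csv"))
  jsonlite::write_json(scalefactors, file.path(spatial, "scalefactors_json.json"),
                       auto_unbox = TRUE, digits = I(17))
  if (!is.null(image)) {
    if (max(image) > 1) image <- image / 255
    png::writePNG(image, file.path(spatial, "tissue_hires_image.png"))
    # community loaders expect the lowres companion; nearest-neighbour downsample
    fac <- scalefactors$tissue_lowres_scalef / scalefactors$tissue_hires_scalef
    if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1))
    ri <- unique(round(seq(1, dim(image)[1], by = 1 / fac)))
    ci <- unique(round(seq(1, dim(image)[2], by = 1 / fac)))
    low <- image[ri, ci, , drop = TRUE]
    png::writePNG(low, file.path(spatial, "tissue_lowres_image.png"))
  }
  invisible(path)
}

#' Filter genes and spots of a Visium dataset
#'
#' Applies, in this fixed order: (1) drop genes matching any
#' `drop_gene_patterns` regex (e.g. `^Rpl`, `^Rps`, `^Mrp`, `^mt-` for
#' ribosomal/mitochondrial genes); (2) drop genes detected (count > 0) in
#' `min_spots_per_gene` or fewer spots (strictly more spots are required to
#' keep a gene); (3) drop spots with total counts of `min_counts_per_spot`
#' or fewer, and spots whose summed counts over each pattern in
#' `max_fraction_patterns` reach that pattern's fraction of the spot total
#' (e.g. >= 10% mitochondrial content removes the spot).
#'
#' @param ds A [visium_dataset()].
#' @param min_counts_per_spot Spots must exceed this total (strict).
#' @param min_spots_per_gene Genes must be detected in more spots (strict).
#' @param drop_gene_patterns Character vector of regexes on gene names.
#' @param max_fraction_patterns Named numeric vector or list of
#'   `(regex = fraction)` pairs in [0, 1].
#' @return A filtered [visium_dataset()].
#' @export
filter_visium <- function(ds, min_counts_per_spot = 0, min_spots_per_gene = 0,
                          drop_gene_patterns = character(),
                          max_fraction_patterns = NULL) {
  stopifnot(inherits(ds, "visium_dataset"),
            min_counts_per_spot >= 0, min_spots_per_gene >= 0)
  counts <- ds$counts
  feat <- ds$features

  # stage 1: gene pattern drop
  if (length(drop_gene_patterns) > 0) {
    drop <- Reduce(`|`, lapply(drop_gene_patterns, function(p) grepl(p, feat$name)))
    counts <- counts[!drop, , drop = FALSE]
    feat <- feat[!drop, ]
    if (nrow(counts) == 0) abort("gene-pattern filter removed all genes")
  }
  # stage 2: gene prevalence (keep genes detected in > min_spots_per_gene spots)
  nspots <- Matrix::rowSums(counts > 0)
  keep_g <- nspots > min_spots_per_gene
  counts <- counts[keep_g, , drop = FALSE]
  feat <- feat[keep_g, ]
  if (nrow(counts) == 0) abort("gene-prevalence filter removed all genes")
  # stage 3: spot filters
  totals <- Matrix::colSums(counts)
  keep_s <- totals > min_counts_per_spot
  if (!is.null(max_fraction_patterns)) {
    fr <- unlist(max_fraction_patterns)
    stopifnot(all(fr >= 0 & fr <= 1))
    for (p in names(fr)) {
      sub <- Matrix::colSums(counts[grepl(p, feat$name), , drop = FALSE])
      frac <- ifelse(totals > 0, sub / totals, 0)
      keep_s <- keep_s & frac < fr[[p]]
    }
  }
  if (!any(keep_s)) abort("spot filter removed all spots")

  visium_dataset(ds$barcodes[keep_s], feat, counts[, keep_s, drop = FALSE],
                 ds$positions[keep_s, ], ds$scalefactors, ds$images)
}
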