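make_bundle_inputs <- function(n_spots = 5, n_feat = 10, seed = 50) {
  withr::with_seed(seed, {
    barcodes <- sprintf("BC%04d-1", seq_len(n_spots))
    feats <- tibble::tibble(id = sprintf("ENS%05d", seq_len(n_feat)),
                            name = sprintf("Gene%02d", seq_len(n_feat)),
                            feature_type = "Gene Expression")
    m <- matrix(rpois(n_feat * n_spots, 3), n_feat, n_spots,
                dimnames = list(feats$id, barcodes))
    pos <- tibble::tibble(barcode = barcodes,
                          in_tissue = rbinom(n_spots, 1, 0.7),
                          array_row = seq_len(n_spots) - 1L,
                          array_col = rev(seq_len(n_spots)) - 1L,
                          pxl_row_in_fullres = runif(n_spots, 0, 1000),
                          pxl_col_in_fullres = runif(n_spots, 0, 1000))
    sf <- list(spot_diameter_fullres = 89.47, tissue_hires_scalef = 0.123456789,
               tissue_lowres_scalef = 0.0370370370370370363)
    list(matrix = m, features = feats, positions = pos, scalefactors = sf,
         barcodes = barcodes)
  })
}

test_that("write then read round-trips matrix, positions and scalefactors exactly", {
  inp <- make_bundle_inputs()
  tmp <- withr::local_tempdir()
  dir <- file.path(tmp, "bundle")
  write_spaceranger_style(inp$matrix, inp$positions, inp$scalefactors, dir,
                          features = inp$features, barcodes = inp$barcodes)
  ds <- read_spaceranger(dir)
  expect_identical(ds$barcodes, inp$barcodes)
  expect_identical(as.matrix(ds$counts), unname(inp$matrix) * 1.0)
  expect_identical(ds$features$id, inp$features$id)
  expect_equal(ds$positions, inp$positions)
  expect_identical(ds$scalefactors$spot_diameter_fullres, inp$scalefactors$spot_diameter_fullres)
  expect_identical(ds$scalefactors$tissue_hires_scalef, inp$scalefactors$tissue_hires_scalef)
  expect_identical(ds$scalefactors$tissue_lowres_scalef, inp$scalefactors$tissue_lowres_scalef)
})

test_that("float intensities and m/z feature names survive the HDF5 round trip", {
  mz_names <- c("89.02435", "218.10372", "550.15724")
  m <- matrix(c(1.25, 0, 3.75, 0.5, 2.125, 0), 3, 2,
              dimnames = list(mz_names, c("A-1", "B-1")))
  pos <- tibble::tibble(barcode = c("A-1", "B-1"), in_tissue = 1L,
                        array_row = 0:1, array_col = 0:1,
                        pxl_row_in_fullres = c(10.5, 20.25), pxl_col_in_fullres = c(1, 2))
  tmp <- withr::local_tempdir()
  dir <- file.path(tmp, "peaks")
  write_spaceranger_style(m, pos, list(spot_diameter_fullres = 50,
                                       tissue_hires_scalef = 0.5,
                                       tissue_lowres_scalef = 0.1),
                          dir, feature_type = "Peak")
  ds <- read_spaceranger(dir)
  expect_identical(ds$features$name, mz_names)
  expect_identical(ds$features$feature_type, rep("Peak", 3))
  expect_identical(as.matrix(ds$counts), unname(m))
})

test_that("the HDF5 shape dataset records features x barcodes", {
  m <- matrix(seq_len(50) * 1.0, 10, 5,
              dimnames = list(sprintf("P%02d", 1:10), sprintf("B%d-1", 1:5)))
  pos <- tibble::tibble(barcode = colnames(m), in_tissue = 1L, array_row = 0:4,
                        array_col = 0:4, pxl_row_in_fullres = 1:5 * 10,
                        pxl_col_in_fullres = 1:5 * 10)
  tmp <- withr::local_tempdir()
  dir <- file.path(tmp, "shape")
  write_spaceranger_style(m, pos, list(spot_diameter_fullres = 5,
                                       tissue_hires_scalef = 1,
                                       tissue_lowres_scalef = 0.3), dir)
  shape <- rhdf5::h5read(file.path(dir, "filtered_feature_bc_matrix.h5"), "matrix/shape")
  rhdf5::H5close()
  expect_equal(as.integer(shape), c(10L, 5L))
})

test_that("both tissue-positions dialects yield identical datasets", {
  inp <- make_bundle_inputs(seed = 51)
  tmp <- withr::local_tempdir()
  dir <- file.path(tmp, "v2")
  write_spaceranger_style(inp$matrix, inp$positions, inp$scalefactors, dir,
                          features = inp$features, barcodes = inp$barcodes)
  ds2 <- read_spaceranger(dir)
  # rewrite the positions in the headerless v1 dialect
  file.rename(file.path(dir, "spatial", "tissue_positions.csv"),
              file.path(tmp, "backup.csv"))
  v1 <- readr::read_csv(file.path(tmp, "backup.csv"), show_col_types = FALSE)
  readr::write_csv(v1, file.path(dir, "spatial", "tissue_positions_list.csv"),
                   col_names = FALSE)
  ds1 <- read_spaceranger(dir)
  expect_equal(ds1$positions, ds2$positions)
  expect_identical(as.matrix(ds1$counts), as.matrix(ds2$counts))
})

test_that("missing files and wrong bundles fail with the filename", {
  inp <- make_bundle_inputs(seed = 52)
  tmp <- withr::local_tempdir()
  dir <- file.path(tmp, "broken")
  write_spaceranger_style(inp$matrix, inp$positions, inp$scalefactors, dir,
                          features = inp$features, barcodes = inp$barcodes)
  file.remove(file.path(dir, "spatial", "scalefactors_json.json"))
  expect_error(read_spaceranger(dir), "scalefactors_json.json")
  expect_error(read_spaceranger(file.path(tmp, "nowhere")), "not found")
})

test_that("positions absent from the matrix are dropped with a message", {
  inp <- make_bundle_inputs(n_spots = 3, seed = 53)
  extra <- dplyr::bind_rows(inp$positions, tibble::tibble(
    barcode = "EXTRA-1", in_tissue = 0L, array_row = 9L, array_col = 9L,
    pxl_row_in_fullres = 1, pxl_col_in_fullres = 1))
  tmp <- withr::local_tempdir()
  dir <- file.path(tmp, "extra")
  write_spaceranger_style(inp$matrix, inp$positions, inp$scalefactors, dir,
                          features = inp$features, barcodes = inp$barcodes)
  readr::write_csv(extra, file.path(dir, "spatial", "tissue_positions.csv"))
  expect_message(ds <- read_spaceranger(dir), "1 position record")
  expect_equal(ncol(ds$counts), 3)
  expect_false("EXTRA-1" %in% ds$positions$barcode)
})

test_that("a large barcode mismatch is a wrong-bundle fatal", {
  inp <- make_bundle_inputs(n_spots = 4, seed = 54)
  tmp <- withr::local_tempdir()
  dir <- file.path(tmp, "mismatch")
  write_spaceranger_style(inp$matrix, inp$positions, inp$scalefactors, dir,
                          features = inp$features, barcodes = inp$barcodes)
  wrong <- inp$positions
  wrong$barcode <- sprintf("OTHER%04d-1", seq_len(4))
  readr::write_csv(wrong, file.path(dir, "spatial", "tissue_positions.csv"))
  expect_error(read_spaceranger(dir), "wrong bundle")
})

test_that("non-finite matrix values are fatal on write", {
  inp <- make_bundle_inputs(n_spots = 2, seed = 55)
  m <- inp$matrix * 1.0
  m[1, 1] <- NaN
  tmp <- withr::local_tempdir()
  expect_error(write_spaceranger_style(m, inp$positions, inp$scalefactors,
                                       file.path(tmp, "nan"),
                                       features = inp$features, barcodes = inp$barcodes),
               "non-finite")
})

test_that("filter_visium applies spot totals, gene patterns and prevalence rules", {
  # spot totals {50, 101, 200}: min_counts_per_spot = 100 keeps the last two
  counts <- rbind(Gene01 = c(20, 51, 80), Gene02 = c(10, 20, 40),
                  Gene03 = c(15, 20, 50), Rpl3 = c(5, 10, 30))
  centers <- cbind(c(0, 100, 200), c(0, 0, 0))
  vis <- make_toy_visium(centers, counts = counts)
  out <- filter_visium(vis, min_counts_per_spot = 100)
  expect_equal(unname(Matrix::colSums(out$counts)), c(101, 200))

  # drop pattern ^Rpl removes Rpl3, keeps the rest
  out2 <- filter_visium(vis, drop_gene_patterns = "^Rpl")
  expect_false("Rpl3" %in% out2$features$name)
  expect_equal(nrow(out2$counts), 3)

  # a gene detected in exactly min_spots_per_gene spots is removed
  counts2 <- rbind(Rare = c(1, 1, 1, 1, 1, 0), Common = rep(5, 6))
  vis2 <- make_toy_visium(cbind(0:5 * 100, 0), counts = counts2)
  out3 <- filter_visium(vis2, min_spots_per_gene = 5)
  expect_equal(out3$features$name, "Common")
  out4 <- filter_visium(vis2, min_spots_per_gene = 4)
  expect_setequal(out4$features$name, c("Rare", "Common"))
})

test_that("fraction-pattern spot filters remove spots at or above the fraction", {
  counts <- rbind(`mt-Co1` = c(10, 9, 30), Gene01 = c(90, 91, 70))
  vis <- make_toy_visium(cbind(c(0, 100, 200), 0), counts = counts)
  out <- filter_visium(vis, max_fraction_patterns = list(`^mt-` = 0.10))
  # fractions {0.10, 0.09, 0.30}: >= 10% removed
  expect_equal(ncol(out$counts), 1)
  expect_equal(unname(Matrix::colSums(out$counts)), 100)
})

test_that("filter_visium is idempotent and fails loudly when nothing survives", {
  scen <- get_scenario()
  f1 <- filter_visium(scen$visium, min_counts_per_spot = 30,
                      min_spots_per_gene = 3, drop_gene_patterns = c("^Rpl", "^mt-"))
  f2 <- filter_visium(f1, min_counts_per_spot = 30,
                      min_spots_per_gene = 3, drop_gene_patterns = c("^Rpl", "^mt-"))
  expect_identical(f1$barcodes, f2$barcodes)
  expect_identical(as.matrix(f1$counts), as.matrix(f2$counts))
  expect_error(filter_visium(scen$visium, min_counts_per_spot = 1e9), "spot filter")
  expect_error(filter_visium(scen$visium, drop_gene_patterns = "."), "all genes")
})
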