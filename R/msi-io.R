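#' MSI peak-by-pixel datasets
#'
#' An `msi_dataset` holds a mass-spectrometry-imaging acquisition as a
#' pixel-by-peak intensity matrix plus per-pixel coordinates and metadata.
#' Peaks are indexed by m/z (Da); pixel coordinates are in the instrument's
#' native units (`pixel_pitch` records the micrometre spacing when known,
#' e.g. 65 for a 65 um DESI raster).
#'
#' @param pixels Tibble with columns `pixel_id`, `x`, `y` plus any metadata
#'   columns (e.g. a tissue/background ROI label).
#' @param mz Numeric vector of peak masses, one per intensity column.
#' @param intensities Numeric matrix, pixels x peaks, non-negative and finite.
#' @param mz_labels Character names for the peaks; defaults to the original
#'   column headers so m/z strings round-trip unchanged.
#' @param pixel_pitch Optional micrometres between adjacent pixel centres.
#' @return An `msi_dataset`.
#' @export
msi_dataset <- function(pixels, mz, intensities, mz_labels = NULL, pixel_pitch = NULL) {
  pixels <- as_tibble(pixels)
  stopifnot(all(c("pixel_id", "x", "y") %in% names(pixels)))
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (length(mz) != ncol(intensities)) {
    stopf("length(mz) (%d) must equal the number of intensity columns (%d)",
          length(mz), ncol(intensities))
  }
  if (nrow(pixels) != nrow(intensities)) abort("one intensity row per pixel required")
  if (any(!is.finite(intensities))) abort("intensities must be finite")
  if (any(intensities < 0)) {
    bad <- which(intensities < 0, arr.ind = TRUE)[1, ]
    stopf("negative intensity at pixel %s, peak %g", pixels$pixel_id[bad[1]], mz[bad[2]])
  }
  if (any(mz <= 0)) abort("m/z values must be strictly positive")
  if (anyDuplicated(pixels[, c("x", "y")])) abort("duplicated pixel coordinates")
  if (is.null(mz_labels)) mz_labels <- format(mz, trim = TRUE)
  structure(
    list(pixels = pixels, mz = as.numeric(mz), intensities = unname(intensities),
         mz_labels = as.character(mz_labels), pixel_pitch = pixel_pitch),
    class = "msi_dataset"
  )
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("<msi_dataset: %d pixels x %d peaks", nrow(x$pixels), length(x$mz)))
  if (!is.null(x$pixel_pitch)) cat(sprintf(", pitch %g um", x$pixel_pitch))
  cat(">\n")
  invisible(x)
}

#' @export
dim.msi_dataset <- function(x) c(nrow(x$pixels), length(x$mz))

#' Read an MSI peak-by-pixel table
#'
#' Reads a delimited table (CSV or TSV by extension) with one row per pixel.
#' Columns whose header parses as a number are taken as peak intensities
#' named by m/z; the coordinate columns and any remaining columns become
#' pixel metadata.  This is the tabular export produced by vendor tools
#' (e.g. SCiLS Lab) or Cardinal.
#'
#' @param path Delimited file.
#' @param x_col,y_col Names of the pixel-coordinate columns.
#' @param pixel_pitch Optional micrometre pitch stored on the dataset.
#' @return An [msi_dataset()].
#' @export
read_peak_table <- function(path, x_col = "x", y_col = "y", pixel_pitch = NULL) {
  if (!file.exists(path)) stopf("MSI peak table not found: %s", path)
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  tab <- reader(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c(x_col, y_col) %in% names(tab))) {
    stopf("coordinate columns '%s'/'%s' not found in %s", x_col, y_col, path)
  }
  headers <- setdiff(names(tab), c(x_col, y_col))
  mz_vals <- suppressWarnings(as.numeric(headers))
  peak_cols <- headers[!is.na(mz_vals)]
  meta_cols <- headers[is.na(mz_vals)]
  if (length(peak_cols) == 0) stopf("no peak columns (numeric m/z headers) in %s", path)
  pixels <- tibble(
    pixel_id = if ("pixel_id" %in% meta_cols) as.character(tab$pixel_id)
               else sprintf("px%06d", seq_len(nrow(tab))),
    x = as.numeric(tab[[x_col]]), y = as.numeric(tab[[y_col]])
  )
  for (mc in setdiff(meta_cols, "pixel_id")) pixels[[mc]] <- tab[[mc]]
  msi_dataset(pixels,
              mz = mz_vals[!is.na(mz_vals)],
              intensities = as.matrix(tab[, peak_cols, drop = FALSE]),
              mz_labels = peak_cols,
              pixel_pitch = pixel_pitch)
}

#' Write an MSI dataset back to a peak table
#' @param ds An [msi_dataset()].
#' @param path Output CSV path.
#' @export
write_peak_table <- function(ds, path) {
  stopifnot(inherits(ds, "msi_dataset"))
  out <- ds$pixels
  mat <- as.data.frame(ds$intensities)
  names(mat) <- ds$mz_labels
  readr::write_csv(dplyr::bind_cols(out, mat), path)
  invisible(path)
}

#' Total-ion-count normalisation
#'
#' Divides each pixel's intensities by that pixel's total ion count, then
#' rescales so per-pixel totals equal a common constant: the median
#' pre-normalisation pixel total by default (keeping magnitudes comparable
#' to the raw data, so intensity thresholds stay meaningful), or 1 with
#' `scale = "unit"`.  Pixels with zero total are dropped with a message.
#'
#' @param ds An [msi_dataset()].
#' @param scale `"median_total"` (default) or `"unit"`.
#' @return A normalised [msi_dataset()].
#' @export
tic_normalize <- function(ds, scale = c("median_total", "unit")) {
  stopifnot(inherits(ds, "msi_dataset"))
  scale <- match.arg(scale)
  totals <- rowSums(ds$intensities)
  keep <- totals > 0
  if (!any(keep)) abort("all pixels have zero total intensity")
  if (any(!keep)) inform(sprintf("tic_normalize: dropped %d zero-total pixel(s)", sum(!keep)))
  target <- if (scale == "median_total") median(totals[keep]) else 1
  ints <- ds$intensities[keep, , drop = FALSE] / totals[keep] * target
  msi_dataset(ds$pixels[keep, , drop = FALSE], ds$mz, ints,
              mz_labels = ds$mz_labels, pixel_pitch = ds$pixel_pitch)
}

#' Combine peaks that share a rounded mass
#'
#' Peaks with the same m/z down to `decimals` decimal places are combined by
#' keeping only the peak with the highest total intensity summed over all
#' pixels of all supplied datasets; ties go to the lower exact mass.  When
#' several datasets are given (multi-sample studies) the totals are summed
#' across them and each dataset is reduced to the same retained peak set.
#'
#' @param ds An [msi_dataset()] or a list of them sharing a peak list.
#' @param decimals Number of decimal places defining "same mass" (default 2).
#' @return A dataset (or list) with a strictly increasing, deduplicated
#'   peak list.
#' @export
deduplicate_peaks <- function(ds, decimals = 2) {
  stopifnot(decimals >= 0)
  single <- inherits(ds, "msi_dataset")
  dss <- if (single) list(ds) else ds
  stopifnot(all(vapply(dss, inherits, logical(1), "msi_dataset")))
  mz <- dss[[1]]$mz
  for (d in dss) if (!identical(d$mz, mz)) abort("datasets must share one peak list")
  totals <- Reduce(`+`, lapply(dss, function(d) colSums(d$intensities)))
  key <- round(mz, decimals)
  ord <- order(key, -totals, mz)          # within a key: highest total, then lower mz
  keep_idx <- sort(ord[!duplicated(key[ord])])
  out <- lapply(dss, function(d) {
    msi_dataset(d$pixels, d$mz[keep_idx], d$intensities[, keep_idx, drop = FALSE],
                mz_labels = d$mz_labels[keep_idx], pixel_pitch = d$pixel_pitch)
  })
  if (single) out[[1]] else out
}

#' Quality-filter MSI pixels and peaks
#'
#' Keeps pixels with strictly more than `min_peaks_per_pixel` detected
#' (strictly positive) peaks AND a total intensity strictly above
#' `min_total_intensity`.  Optionally restricts the peak list to masses
#' matching `keep_mz` within 1e-6 Da.  Thresholds are study-specific user
#' parameters: published cutoffs apply to vendor-normalised intensity
#' scales that differ between instruments.
#'
#' @param ds An [msi_dataset()].
#' @param min_peaks_per_pixel Pixels must exceed this count of nonzero peaks.
#' @param min_total_intensity Pixels must exceed this summed intensity.
#' @param keep_mz Optional numeric vector of masses to retain.
#' @return A filtered [msi_dataset()] (a submatrix of the input).
#' @export
filter_msi <- function(ds, min_peaks_per_pixel = 0, min_total_intensity = 0,
                       keep_mz = NULL) {
  stopifnot(inherits(ds, "msi_dataset"),
            min_peaks_per_pixel >= 0, min_total_intensity >= 0)
  ints <- ds$intensities
  mz <- ds$mz
  labels <- ds$mz_labels
  if (!is.null(keep_mz)) {
    hit <- vapply(mz, function(m) any(abs(m - keep_mz) <= 1e-6), logical(1))
    if (!any(hit)) stopf("no peaks match keep_mz (nearest is %g)",
                         mz[which.min(vapply(mz, function(m) min(abs(m - keep_mz)), numeric(1)))])
    ints <- ints[, hit, drop = FALSE]
    mz <- mz[hit]; labels <- labels[hit]
  }
  npeaks <- rowSums(ints > 0)
  totals <- rowSums(ints)
  keep <- npeaks > min_peaks_per_pixel & totals > min_total_intensity
  if (!any(keep)) {
    stopf("all %d pixels removed (%d failed the peak-count filter, %d the intensity filter)",
          length(keep), sum(npeaks <= min_peaks_per_pixel), sum(totals <= min_total_intensity))
  }
  msi_dataset(ds$pixels[keep, , drop = FALSE], mz, ints[keep, , drop = FALSE],
              mz_labels = labels, pixel_pitch = ds$pixel_pitch)
}

#' Long-format view of an MSI dataset
#' @param x An [msi_dataset()].
#' @param ... Unused.
#' @export
as_tibble.msi_dataset <- function(x, ...) {
  wide <- dplyr::bind_cols(x$pixels, setNames(as.data.frame(x$intensities), x$mz_labels))
  tidyr::pivot_longer(wide, cols = all_of(x$mz_labels),
                      names_to = "mz", values_to = "intensity") |>
    mutate(mz = as.numeric(.data$mz))
}
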