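#' Data-generated MSI images
#'
#' An `msi_image` is a rasterisation of per-pixel MSI values into an image
#' used for landmark selection.  The `frame` records how raster (row, col)
#' cells map back to MSI native (x, y) coordinates: `x = x0 + (col-1) *
#' xstep`, `y = y0 + (row-1) * ystep`, with y increasing downward (image
#' convention).  Raster values live in [0, 255]; cells with no MSI pixel
#' are background-filled and flagged in `filled`.
#'
#' @name msi_image
NULL

new_msi_image <- function(raster, frame, filled, channel_sources) {
  structure(list(raster = raster, frame = frame, filled = filled,
                 channel_sources = channel_sources),
            class = "msi_image")
}

#' @export
print.msi_image <- function(x, ...) {
  d <- dim(x$raster)
  cat(sprintf("<msi_image: %d x %d x %d (%s)>\n", d[1], d[2], d[3],
              paste(x$channel_sources, collapse = ", ")))
  invisible(x)
}

infer_grid_step <- function(v) {
  u <- sort(unique(v))
  if (length(u) < 2) return(1)
  d <- diff(u)
  step <- median(d[d > 0])
  if (!is.finite(step) || step <= 0) abort("degenerate pixel coordinates: cannot infer grid step")
  step
}

#' Rasterize per-pixel values onto the MSI grid
#'
#' Places each pixel's value at its raster cell.  The grid step per axis is
#' inferred as the median positive difference of the sorted unique
#' coordinates, so the raster is correct for rectilinear acquisitions with
#' missing pixels.
#'
#' @param ds An [msi_dataset()].
#' @param values Numeric vector (one per pixel) or matrix (pixels x
#'   channels, up to 3 channels).
#' @param channel_sources Character description of each channel.
#' @param fill Fill value for cells without a pixel (default 0).
#' @return An [msi_image()].
#' @export
msi_rasterize <- function(ds, values, channel_sources = NULL, fill = 0) {
  stopifnot(inherits(ds, "msi_dataset"))
  if (is.vector(values)) values <- matrix(values, ncol = 1)
  stopifnot(nrow(values) == nrow(ds$pixels), ncol(values) <= 3)
  x <- ds$pixels$x; y <- ds$pixels$y
  xstep <- infer_grid_step(x); ystep <- infer_grid_step(y)
  x0 <- min(x); y0 <- min(y)
  col <- as.integer(round((x - x0) / xstep)) + 1L
  row <- as.integer(round((y - y0) / ystep)) + 1L
  if (anyDuplicated(cbind(row, col))) abort("multiple pixels map to one raster cell")
  H <- max(row); W <- max(col)
  raster <- array(fill, dim = c(H, W, ncol(values)))
  filled <- matrix(FALSE, H, W)
  filled[cbind(row, col)] <- TRUE
  for (ch in seq_len(ncol(values))) {
    plane <- matrix(fill, H, W)
    plane[cbind(row, col)] <- values[, ch]
    raster[, , ch] <- plane
  }
  new_msi_image(raster,
                frame = list(x0 = x0, y0 = y0, xstep = xstep, ystep = ystep),
                filled = filled,
                channel_sources = channel_sources %||% paste0("channel", seq_len(ncol(values))))
}

#' Convert raster cells back to MSI native coordinates
#' @param img An [msi_image()].
#' @param cells Matrix/data frame of (row, col) raster indices (1-based).
#' @return Tibble with `x`, `y` native coordinates.
#' @export
raster_to_native <- function(img, cells) {
  stopifnot(inherits(img, "msi_image"))
  cells <- as.matrix(as.data.frame(cells))
  tibble(x = img$frame$x0 + (cells[, 2] - 1) * img$frame$xstep,
         y = img$frame$y0 + (cells[, 1] - 1) * img$frame$ystep)
}

# PCA scores with a deterministic sign convention: for each component the
# loading of largest absolute value is made positive.  Centering only by
# default; unit-variance scaling is a flag.
msi_pca_scores <- function(ds, n_components, scale. = FALSE) {
  if (nrow(ds$pixels) < 2) abort("PCA needs at least 2 pixels")
  if (length(ds$mz) < n_components) {
    stopf("n_components = %d exceeds the %d available peaks", n_components, length(ds$mz))
  }
  if (all(apply(ds$intensities, 2, var) < .Machine$double.eps)) {
    abort("constant-intensity dataset: no variance for PCA")
  }
  p <- prcomp(ds$intensities, center = TRUE, scale. = scale., rank. = n_components)
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  p
}

clip_rescale <- function(v, clip_percentiles = c(1, 99)) {
  lo <- quantile(v, clip_percentiles[1] / 100, names = FALSE)
  hi <- quantile(v, clip_percentiles[2] / 100, names = FALSE)
  v <- pmin(pmax(v, lo), hi)
  if (hi > lo) (v - lo) / (hi - lo) * 255 else rep(0, length(v))
}

#' Principal-component RGB image of an MSI dataset
#'
#' Computes the top 1-3 principal components of the (mean-centred) peak
#' matrix, clips each component at the stated percentiles, rescales to
#' [0, 255] and assigns them to the R, G, B channels in component order.
#' Sign indeterminacy is fixed by forcing each component's largest-|loading|
#' to be positive, so the image is deterministic.
#'
#' @param ds An [msi_dataset()].
#' @param n_components 1 to 3 components.
#' @param clip_percentiles Two percentiles used to clip each component.
#' @param scale. Scale peaks to unit variance before PCA (default FALSE:
#'   centring only, so high-intensity structural peaks dominate and tissue
#'   boundaries stay visible).
#' @return An [msi_image()] with 3 channels (unused channels are zero).
#' @export
pca_rgb_image <- function(ds, n_components = 3, clip_percentiles = c(1, 99),
                          scale. = FALSE) {
  stopifnot(inherits(ds, "msi_dataset"), n_components %in% 1:3)
  p <- msi_pca_scores(ds, n_components, scale.)
  vals <- matrix(0, nrow(ds$pixels), 3)
  for (j in seq_len(n_components)) vals[, j] <- clip_rescale(p$x[, j], clip_percentiles)
  msi_rasterize(ds, vals,
                channel_sources = c(paste0("PC", seq_len(n_components)),
                                    rep("unused", 3 - n_components)))
}

#' Single-peak grayscale image
#'
#' Renders one peak's intensity, capped at `cap_percentile` then scaled to
#' [0, 255] — the way a known spatially informative compound (drug
#' deposition, a structural lipid) is displayed for landmark selection.
#'
#' @param ds An [msi_dataset()].
#' @param mz Peak mass; must match a dataset peak within 1e-6 Da.
#' @param cap_percentile Upper percentile cap (default 99).
#' @return A single-channel [msi_image()].
#' @export
single_peak_image <- function(ds, mz, cap_percentile = 99) {
  stopifnot(inherits(ds, "msi_dataset"))
  d <- abs(ds$mz - mz)
  j <- which.min(d)
  if (d[j] > 1e-6) stopf("no peak at m/z %g (nearest is %g)", mz, ds$mz[j])
  v <- ds$intensities[, j]
  cap <- quantile(v, cap_percentile / 100, names = FALSE)
  v <- pmin(v, cap)
  v <- if (max(v) > min(v)) (v - min(v)) / (max(v) - min(v)) * 255 else rep(0, length(v))
  msi_rasterize(ds, v, channel_sources = sprintf("m/z %s", format(ds$mz[j])))
}

#' Tissue/background labels from the first principal component
#'
#' Computes PC1 as in [pca_rgb_image()], orients it so the class with the
#' higher mean total ion intensity is "tissue", and thresholds it.  With
#' `threshold = "otsu"` the threshold maximises the between-class variance
#' on the 256-bin quantised PC1 histogram.
#'
#' @param ds An [msi_dataset()].
#' @param threshold A number on the PC1 scale, or `"otsu"`.
#' @return Character vector (`"tissue"`/`"background"`), one per pixel.
#' @export
tissue_labels_from_pc1 <- function(ds, threshold = "otsu") {
  stopifnot(inherits(ds, "msi_dataset"))
  pc1 <- msi_pca_scores(ds, 1)$x[, 1]
  totals <- rowSums(ds$intensities)
  # orient PC1 so the high-total-intensity side is positive (= tissue side)
  if (sum(totals[pc1 > median(pc1)]) < sum(totals[pc1 <= median(pc1)])) pc1 <- -pc1
  thr <- if (identical(threshold, "otsu")) otsu_threshold(pc1) else as.numeric(threshold)
  labs <- ifelse(pc1 > thr, "tissue", "background")
  if (length(unique(labs)) == 1) {
    warn("degenerate threshold: all pixels received one label")
  }
  labs
}

# Otsu's method on a 256-bin quantisation of v: exhaustive search over bin
# boundaries for the split maximising between-class variance.
otsu_threshold <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  bins <- pmin(as.integer((v - rng[1]) / diff(rng) * 256), 255L)
  counts <- tabulate(bins + 1L, nbins = 256L)
  p <- counts / sum(counts)
  centers <- rng[1] + (seq_len(256) - 0.5) / 256 * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[256]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  rng[1] + k / 256 * diff(rng)   # upper edge of bin k: "above threshold" = tissue
}

#' Write an MSI image as PNG with a frame sidecar
#'
#' The sidecar JSON records the raster frame (offsets, steps, channel
#' sources) so landmark pixel coordinates picked on the PNG are convertible
#' back to MSI native coordinates exactly.
#'
#' @param img An [msi_image()].
#' @param path PNG path; the sidecar is written at `<path>.json`.
#' @export
write_msi_image <- function(img, path) {
  stopifnot(inherits(img, "msi_image"))
  arr <- img$raster / 255
  if (dim(arr)[3] == 1) arr <- arr[, , 1]
  png::writePNG(arr, path)
  jsonlite::write_json(
    list(frame = img$frame, channel_sources = img$channel_sources),
    paste0(path, ".json"), auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Plot an MSI image
#' @param object An [msi_image()].
#' @param ... Unused.
#' @export
autoplot.msi_image <- function(object, ...) {
  d <- dim(object$raster)
  df <- tidyr::expand_grid(col = seq_len(d[2]), row = seq_len(d[1]))
  if (d[3] >= 3) {
    df$fill <- grDevices::rgb(object$raster[, , 1] / 255,
                              object$raster[, , 2] / 255,
                              object$raster[, , 3] / 255)
    ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$fill)) +
      ggplot2::geom_raster() + ggplot2::scale_fill_identity() +
      ggplot2::scale_y_reverse() + ggplot2::coord_equal() +
      ggplot2::theme_void()
  } else {
    df$value <- as.vector(object$raster[, , 1])
    ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::scale_y_reverse() + ggplot2::coord_equal() +
      ggplot2::labs(fill = object$channel_sources[1]) +
      ggplot2::theme_void()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
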