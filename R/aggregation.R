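#' Spot radius for pixel aggregation
#'
#' Three radius conventions are supported for matching MSI pixels to Visium
#' spots:
#' * `"expanded"` (default): half the minimum pairwise centre distance
#'   among spots, computed by nearest-neighbour search.  Expanded discs
#'   tile the array without intersecting, so every pixel is assigned to at
#'   most one spot.
#' * `"visium"`: the physical spot radius, `spot_diameter_fullres / 2` —
#'   preferable when the MSI raster is much finer than the spot array.
#' * `"msi"`: half an MSI pixel footprint expressed in full-resolution
#'   pixels, `(pixel_pitch / 55) * spot_diameter_fullres / 2` (a Visium
#'   spot is 55 um across) — for MSI coarser than Visium, where one pixel
#'   should contribute to several spots.
#'
#' @param visium A [visium_dataset()].
#' @param msi An [msi_dataset()] with known `pixel_pitch` (only for
#'   `mode = "msi"`).
#' @param mode Radius convention.
#' @return Radius in full-resolution pixels.
#' @export
compute_spot_radius <- function(visium, msi = NULL,
                                mode = c("expanded", "visium", "msi")) {
  mode <- match.arg(mode)
  stopifnot(inherits(visium, "visium_dataset"))
  sf <- visium$scalefactors
  switch(mode,
    expanded = {
      ctr <- as.matrix(spot_centers(visium)[, c("x", "y")])
      if (nrow(ctr) < 2) abort("expanded radius needs at least 2 spots")
      nn <- RANN::nn2(ctr, ctr, k = 2)
      min(nn$nn.dists[, 2]) / 2
    },
    visium = sf$spot_diameter_fullres / 2,
    msi = {
      if (is.null(msi) || is.null(msi$pixel_pitch)) {
        abort("mode 'msi' needs an msi_dataset with a known pixel_pitch")
      }
      (msi$pixel_pitch / 55) * sf$spot_diameter_fullres / 2
    }
  )
}

#' Assign transformed MSI pixels to Visium spots
#'
#' Coordinates must already be in the Visium full-resolution frame.  In
#' `"expanded"`/`"visium"` modes a pixel is assigned to the nearest spot
#' centre within `radius` (ties broken by the lexicographically smallest
#' barcode); each pixel serves at most one spot.  In `"msi"` mode each
#' pixel is a disc of the given radius and contributes to every spot
#' centre it covers, so one pixel may serve several spots.  Pixels
#' assigned nowhere are reported in `unassigned`.
#'
#' @param visium A [visium_dataset()].
#' @param msi_coords_fullres Per-pixel (x, y) matrix/data frame in the
#'   full-resolution frame.
#' @param radius Radius in full-resolution pixels (see
#'   [compute_spot_radius()]).
#' @param mode Radius convention used (controls assignment multiplicity).
#' @param pixel_ids Optional pixel identifiers (default `px000001`...).
#' @return A `spot_pixel_mapping`: list with `assignments` (tibble
#'   `barcode`, `pixel_id`, `distance`), `unassigned` (pixel ids),
#'   `radius`, `mode`, and `barcodes` (the full Visium barcode universe).
#' @export
map_pixels_to_spots <- function(visium, msi_coords_fullres, radius,
                                mode = c("expanded", "visium", "msi"),
                                pixel_ids = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(visium, "visium_dataset"), radius > 0)
  xy <- as_xy_matrix(msi_coords_fullres, "msi_coords_fullres")
  if (is.null(pixel_ids)) pixel_ids <- sprintf("px%06d", seq_len(nrow(xy)))
  ctr <- spot_centers(visium)
  centers <- as.matrix(ctr[, c("x", "y")])

  if (mode %in% c("expanded", "visium")) {
    # nearest spots per pixel; enough neighbours to resolve distance ties
    k <- min(nrow(centers), 4L)
    nn <- RANN::nn2(centers, xy, k = k)
    d1 <- nn$nn.dists[, 1]
    pick <- nn$nn.idx[, 1]
    if (k > 1) {
      # exact-tie rule: among equidistant nearest spots take the smallest barcode
      tied <- which(abs(nn$nn.dists[, 2] - d1) <= 1e-9 * pmax(d1, 1))
      for (i in tied) {
        cand <- nn$nn.idx[i, abs(nn$nn.dists[i, ] - d1[i]) <= 1e-9 * max(d1[i], 1)]
        pick[i] <- cand[order(ctr$barcode[cand])[1]]
      }
    }
    within <- d1 <= radius
    assignments <- tibble(
      barcode = ctr$barcode[pick[within]],
      pixel_id = pixel_ids[within],
      distance = d1[within]
    )
    unassigned <- pixel_ids[!within]
  } else {
    # msi mode: every spot centre covered by the pixel's disc
    k <- min(nrow(xy), 256L)
    repeat {
      nn <- RANN::nn2(xy, centers, k = k, searchtype = "radius", radius = radius)
      if (all(nn$nn.idx[, k] == 0) || k == nrow(xy)) break
      k <- min(nrow(xy), k * 4L)   # some spot saturated the neighbour budget
    }
    hits <- which(nn$nn.idx > 0, arr.ind = TRUE)
    assignments <- tibble(
      barcode = ctr$barcode[hits[, 1]],
      pixel_id = pixel_ids[nn$nn.idx[hits]],
      distance = nn$nn.dists[hits]
    ) |> arrange(.data$barcode, .data$distance)
    unassigned <- setdiff(pixel_ids, assignments$pixel_id)
  }

  if (nrow(assignments) == 0) {
    abort("no pixel lies within any spot radius: registration likely failed")
  }
  if (mode == "expanded" && anyDuplicated(assignments$pixel_id)) {
    abort("internal error: pixel assigned to two spots in expanded mode")
  }
  structure(
    list(assignments = assignments, unassigned = unassigned,
         radius = radius, mode = mode, barcodes = ctr$barcode),
    class = "spot_pixel_mapping"
  )
}

#' @export
print.spot_pixel_mapping <- function(x, ...) {
  cat(sprintf("<spot_pixel_mapping: %d assignments over %d spots (%s, radius %.2f px), %d unassigned>\n",
              nrow(x$assignments), length(unique(x$assignments$barcode)),
              x$mode, x$radius, length(x$unassigned)))
  invisible(x)
}

#' Aggregate mapped MSI pixels into one observation per spot
#'
#' Reduces the pixels assigned to each Visium barcode to a single peak
#' vector: `"sum"`, `"mean"`, or `"weighted_average"` with inverse-distance
#' weights \eqn{w_i = 1 / (d_i + \epsilon)}, \eqn{\epsilon = 10^{-6} \times
#' radius} (bounded at distance zero).  Every Visium barcode appears in the
#' output; spots with no assigned pixel carry an all-zero row and are
#' flagged.
#'
#' @param mapping A [map_pixels_to_spots()] result.
#' @param msi The [msi_dataset()] the pixel ids refer to.
#' @param fn Aggregation function name.
#' @return A `multimodal_matrix`: list with `barcodes`, `mz`, `mz_labels`,
#'   `values` (barcode x peak matrix), `empty_spots` (logical), and
#'   `provenance`.
#' @export
aggregate_pixels <- function(mapping, msi, fn = c("sum", "mean", "weighted_average")) {
  fn <- match.arg(fn)
  stopifnot(inherits(mapping, "spot_pixel_mapping"), inherits(msi, "msi_dataset"))
  a <- mapping$assignments
  pix_idx <- match(a$pixel_id, msi$pixels$pixel_id)
  if (anyNA(pix_idx)) abort("mapping refers to pixels absent from the MSI dataset")

  barcodes <- mapping$barcodes
  spot_idx <- match(a$barcode, barcodes)
  nb <- length(barcodes); np <- length(msi$mz)
  ints <- msi$intensities[pix_idx, , drop = FALSE]

  values <- matrix(0, nb, np)
  if (fn == "sum") {
    agg <- rowsum(ints, group = spot_idx)
    values[as.integer(rownames(agg)), ] <- agg
  } else if (fn == "mean") {
    agg <- rowsum(ints, group = spot_idx)
    cnt <- tabulate(spot_idx, nbins = nb)
    rows <- as.integer(rownames(agg))
    values[rows, ] <- agg / cnt[rows]
  } else {
    eps <- 1e-6 * mapping$radius
    w <- 1 / (a$distance + eps)
    agg <- rowsum(ints * w, group = spot_idx)
    wsum <- rowsum(w, group = spot_idx)
    rows <- as.integer(rownames(agg))
    values[rows, ] <- agg / as.vector(wsum)
  }
  dimnames(values) <- list(barcodes, msi$mz_labels)
  empty <- tabulate(spot_idx, nbins = nb) == 0
  structure(
    list(barcodes = barcodes, mz = msi$mz, mz_labels = msi$mz_labels,
         values = values, empty_spots = setNames(empty, barcodes),
         provenance = list(fn = fn, radius_mode = mapping$mode, radius = mapping$radius)),
    class = "multimodal_matrix"
  )
}

#' @export
print.multimodal_matrix <- function(x, ...) {
  cat(sprintf("<multimodal_matrix: %d spots x %d peaks (%s, %s radius; %d empty spots)>\n",
              length(x$barcodes), length(x$mz), x$provenance$fn,
              x$provenance$radius_mode, sum(x$empty_spots)))
  invisible(x)
}

#' Tidy views of mappings and multimodal matrices
#' @param x A `spot_pixel_mapping` or `multimodal_matrix`.
#' @param ... Unused.
#' @export
tidy.spot_pixel_mapping <- function(x, ...) x$assignments

#' @rdname tidy.spot_pixel_mapping
#' @export
as_tibble.multimodal_matrix <- function(x, ...) {
  df <- as_tibble(as.data.frame(x$values))
  names(df) <- x$mz_labels
  dplyr::bind_cols(tibble(barcode = x$barcodes, empty = unname(x$empty_spots)), df)
}

#' Export a pixel-to-spot mapping as CSV
#' @param mapping A `spot_pixel_mapping`.
#' @param path Output CSV.
#' @export
write_mapping <- function(mapping, path) {
  readr::write_csv(mapping$assignments, path)
  invisible(path)
}

#' Write an aggregated multimodal matrix as a Space Ranger-style bundle
#'
#' Peaks become features of type `"Peak"` named by their m/z strings; the
#' Visium sample's positions and scale factors are reused so both
#' modalities overlay in the same full-resolution frame, with
#' `spot_diameter_fullres` replaced by the aggregation diameter.
#'
#' @param mm A `multimodal_matrix`.
#' @param visium The matching [visium_dataset()].
#' @param path Output directory.
#' @param image Optional transformed image to place in `spatial/`.
#' @export
write_multimodal_bundle <- function(mm, visium, path, image = NULL) {
  stopifnot(inherits(mm, "multimodal_matrix"), inherits(visium, "visium_dataset"))
  feats <- tibble(id = mm$mz_labels, name = mm$mz_labels, feature_type = "Peak")
  sf <- visium$scalefactors
  sf$spot_diameter_fullres <- 2 * mm$provenance$radius
  pos <- visium$positions[match(mm$barcodes, visium$positions$barcode), ]
  write_spaceranger_style(t(mm$values), pos, sf, path,
                          features = feats, barcodes = mm$barcodes, image = image)
}
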