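#' Spatial transforms from landmark pairs
#'
#' A `spatial_transform` maps 2-D points from one coordinate frame into
#' another.  Two kinds are supported: `"affine"` (six parameters, fitted by
#' least squares over all landmark pairs) and `"tps"` (thin-plate spline,
#' an exact interpolating warp through the landmarks when the bending
#' regularisation is zero).  Compositions of transforms are represented as a
#' `"chain"` that applies its members in sequence; a chain of two affines
#' collapses to a single affine matrix.
#'
#' Points are `(x, y)` with `x` the column direction and `y` the row
#' direction, origin top-left, matching image-pixel conventions.
#'
#' @name spatial_transform
NULL

new_spatial_transform <- function(kind, ..., domain_frame = NULL, codomain_frame = NULL) {
  structure(
    list(kind = kind, ..., domain_frame = domain_frame, codomain_frame = codomain_frame),
    class = "spatial_transform"
  )
}

#' Estimate an affine or thin-plate-spline transform from landmarks
#'
#' Fits the geometric transform taking landmark source points onto their
#' target points.  The affine fit minimises the summed squared residual over
#' all pairs; the TPS fit interpolates every pair exactly when
#' `regularization = 0` (the default), with the radial kernel
#' \eqn{U(r) = r^2 \log r^2}.
#'
#' @param landmarks A data frame with columns `source_x`, `source_y`,
#'   `target_x`, `target_y` (one row per landmark pair), as written by
#'   [write_landmarks()].
#' @param kind `"affine"` or `"tps"`.
#' @param regularization Non-negative bending regularisation for TPS;
#'   `0` gives exact interpolation, larger values smooth noisy landmarks.
#' @param domain_frame,codomain_frame Optional frame names carried along and
#'   checked by [compose_transforms()].
#' @return A `spatial_transform` object.
#' @examples
#' lm <- tibble::tibble(source_x = c(0, 1, 0, 1), source_y = c(0, 0, 1, 1),
#'                      target_x = c(10, 11, 10, 11), target_y = c(5, 5, 6, 6))
#' tr <- estimate_transform(lm, "affine")
#' apply_transform(tr, cbind(0.5, 0.5))
#' @export
estimate_transform <- function(landmarks, kind = c("affine", "tps"),
                               regularization = 0,
                               domain_frame = NULL, codomain_frame = NULL) {
  kind <- match.arg(kind)
  lm <- validate_landmarks(landmarks)
  src <- as.matrix(lm[, c("source_x", "source_y")])
  dst <- as.matrix(lm[, c("target_x", "target_y")])
  n <- nrow(src)

  min_n <- if (kind == "affine") 3L else 4L
  if (n < min_n) {
    stopf("%s transform needs at least %d landmark pairs, got %d", kind, min_n, n)
  }
  # collinearity check: rank of centred source configuration must be 2
  sv <- svd(scale(src, center = TRUE, scale = FALSE))$d
  if (sv[2] < 1e-9 * max(sv[1], 1)) {
    abort("landmark source points are collinear; the transform is degenerate")
  }

  if (kind == "affine") {
    # [x' y'] = [x y 1] %*% B with B 3x2; least squares over all pairs
    X <- cbind(src, 1)
    B <- qr.solve(X, dst)
    m <- rbind(t(B), c(0, 0, 1))
    dimnames(m) <- NULL
    tr <- new_spatial_transform("affine", matrix = m,
                                domain_frame = domain_frame,
                                codomain_frame = codomain_frame)
  } else {
    tr <- fit_tps(src, dst, regularization,
                  domain_frame = domain_frame, codomain_frame = codomain_frame)
  }
  tr
}

validate_landmarks <- function(landmarks) {
  needed <- c("source_x", "source_y", "target_x", "target_y")
  if (!is.data.frame(landmarks) || !all(needed %in% names(landmarks))) {
    abort("`landmarks` must be a data frame with columns source_x, source_y, target_x, target_y")
  }
  lm <- as_tibble(landmarks)[, needed]
  if (!all(vapply(lm, is.numeric, logical(1))) || !all(is.finite(as.matrix(lm)))) {
    abort("landmark coordinates must be finite numbers")
  }
  if (anyDuplicated(lm[, c("source_x", "source_y")])) {
    abort("duplicated landmark source points")
  }
  lm
}

tps_kernel <- function(r2) {
  # U(r) = r^2 log r^2, with U(0) = 0
  k <- r2 * log(r2)
  k[r2 == 0] <- 0
  k
}

fit_tps <- function(src, dst, regularization = 0, domain_frame = NULL, codomain_frame = NULL) {
  n <- nrow(src)
  # normalise source coordinates (centre + RMS scale) before building the
  # system: raw pixel coordinates in the thousands make L ill-conditioned
  center <- colMeans(src)
  scl <- sqrt(mean(rowSums(sweep(src, 2, center)^2)))
  if (!is.finite(scl) || scl <= 0) scl <- 1
  sn <- sweep(src, 2, center) / scl
  d2 <- outer(sn[, 1], sn[, 1], "-")^2 + outer(sn[, 2], sn[, 2], "-")^2
  K <- tps_kernel(d2) + diag(regularization, n)
  P <- cbind(1, sn)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(dst, matrix(0, 3, 2))
  coef <- unname(solve(L, rhs))
  new_spatial_transform(
    "tps",
    control_src = unname(src), control_dst = unname(dst),
    norm_center = unname(center), norm_scale = scl,
    weights = coef[seq_len(n), , drop = FALSE],
    affine_part = coef[n + 1:3, , drop = FALSE],
    regularization = regularization,
    domain_frame = domain_frame, codomain_frame = codomain_frame
  )
}

#' Apply a spatial transform to points
#'
#' @param transform A `spatial_transform`.
#' @param points A 2-column matrix, or a data frame with `x`/`y` columns
#'   (a data frame in gives a tibble back with the same extra columns).
#' @return Transformed points in the same shape as the input.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "spatial_transform"))
  if (is.data.frame(points)) {
    xy <- as_xy_matrix(points)
    out <- apply_transform(transform, xy)
    res <- as_tibble(points)
    res$x <- out[, 1]
    res$y <- out[, 2]
    return(res)
  }
  pts <- as_xy_matrix(points)
  switch(transform$kind,
    affine = {
      h <- cbind(pts, 1) %*% t(transform$matrix)
      h[, 1:2, drop = FALSE]
    },
    tps = {
      sn <- sweep(transform$control_src, 2, transform$norm_center) / transform$norm_scale
      pn <- sweep(pts, 2, transform$norm_center) / transform$norm_scale
      d2 <- outer(pn[, 1], sn[, 1], "-")^2 + outer(pn[, 2], sn[, 2], "-")^2
      U <- tps_kernel(d2)
      cbind(1, pn) %*% transform$affine_part + U %*% transform$weights
    },
    chain = {
      for (t in transform$transforms) pts <- apply_transform(t, pts)
      pts
    },
    stopf("unknown transform kind '%s'", transform$kind)
  )
}

#' Compose two spatial transforms
#'
#' `compose_transforms(outer, inner)` returns the transform equivalent to
#' applying `inner` first, then `outer` — the two-stage registration chain
#' (data-generated image -> microscopy image -> Visium image) composes this
#' way.  Two affines collapse into one affine matrix; any composition
#' involving a TPS is kept as a chained applicator.
#'
#' @param outer,inner `spatial_transform` objects; `inner`'s codomain frame
#'   must match `outer`'s domain frame when both are set.
#' @return A `spatial_transform`.
#' @export
compose_transforms <- function(outer, inner) {
  stopifnot(inherits(outer, "spatial_transform"), inherits(inner, "spatial_transform"))
  if (!is.null(inner$codomain_frame) && !is.null(outer$domain_frame) &&
      !identical(inner$codomain_frame, outer$domain_frame)) {
    stopf("frame mismatch: inner maps into '%s' but outer expects '%s'",
          inner$codomain_frame, outer$domain_frame)
  }
  if (outer$kind == "affine" && inner$kind == "affine") {
    return(new_spatial_transform("affine", matrix = outer$matrix %*% inner$matrix,
                                 domain_frame = inner$domain_frame,
                                 codomain_frame = outer$codomain_frame))
  }
  flatten <- function(t) if (t$kind == "chain") t$transforms else list(t)
  new_spatial_transform("chain",
                        transforms = c(flatten(inner), flatten(outer)),
                        domain_frame = inner$domain_frame,
                        codomain_frame = outer$codomain_frame)
}

#' Identity transform
#' @param frame Optional frame name used for both domain and codomain.
#' @return An affine `spatial_transform` equal to the identity map.
#' @export
identity_transform <- function(frame = NULL) {
  new_spatial_transform("affine", matrix = diag(3),
                        domain_frame = frame, codomain_frame = frame)
}

#' Invert a spatial transform
#'
#' Affine transforms invert exactly.  A TPS has no closed-form inverse; the
#' inverse is approximated by fitting a fresh TPS on the swapped landmark
#' pairs, which is adequate for mild warps (used for backward image warping).
#'
#' @param transform A `spatial_transform`.
#' @return A `spatial_transform` mapping the codomain back to the domain.
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "spatial_transform"))
  switch(transform$kind,
    affine = {
      d <- det(transform$matrix[1:2, 1:2])
      if (!is.finite(d) || abs(d) < 1e-12) abort("affine transform is not invertible")
      new_spatial_transform("affine", matrix = solve(transform$matrix),
                            domain_frame = transform$codomain_frame,
                            codomain_frame = transform$domain_frame)
    },
    tps = fit_tps(transform$control_dst, transform$control_src,
                  transform$regularization,
                  domain_frame = transform$codomain_frame,
                  codomain_frame = transform$domain_frame),
    chain = {
      inv <- lapply(rev(transform$transforms), invert_transform)
      new_spatial_transform("chain", transforms = inv,
                            domain_frame = transform$codomain_frame,
                            codomain_frame = transform$domain_frame)
    }
  )
}

#' Warp a raster into a target frame
#'
#' Backward warping: every target cell centre is mapped through the inverse
#' transform into the source raster and bilinearly interpolated.  Cells that
#' land outside the source are filled with `fill` and flagged.
#'
#' @param img A numeric matrix (H x W) or array (H x W x C), or an
#'   [msi_image()].
#' @param transform `spatial_transform` mapping source (x, y) pixel
#'   coordinates into target (x, y) pixel coordinates.
#' @param target_shape Integer `(height, width)` of the output raster.
#' @param fill Value for out-of-source cells (default 0).
#' @return A list with `raster` (H x W x C array) and `inside` (logical
#'   H x W matrix flagging cells covered by the source image).
#' @export
transform_image <- function(img, transform, target_shape, fill = 0) {
  if (inherits(img, "msi_image")) img <- img$raster
  if (is.matrix(img)) img <- array(img, dim = c(dim(img), 1))
  stopifnot(length(dim(img)) == 3, length(target_shape) == 2)
  H <- as.integer(target_shape[1]); W <- as.integer(target_shape[2])
  inv <- invert_transform(transform)
  # target cell centres, 0-based pixel coordinates (x = col, y = row)
  grid <- cbind(x = rep(seq_len(W) - 1, each = H), y = rep(seq_len(H) - 1, times = W))
  srcxy <- apply_transform(inv, grid)
  out <- array(fill, dim = c(H, W, dim(img)[3]))
  sh <- dim(img)[1]; sw <- dim(img)[2]
  x <- srcxy[, 1]; y <- srcxy[, 2]
  inside <- x >= 0 & x <= sw - 1 & y >= 0 & y <= sh - 1
  x0 <- pmax(pmin(floor(x), sw - 2), 0); y0 <- pmax(pmin(floor(y), sh - 2), 0)
  fx <- x - x0; fy <- y - y0
  for (ch in seq_len(dim(img)[3])) {
    plane <- img[, , ch]
    idx <- function(r, c) plane[cbind(r + 1, c + 1)]
    v <- (1 - fx) * (1 - fy) * idx(y0, x0) +
      fx * (1 - fy) * idx(y0, x0 + 1) +
      (1 - fx) * fy * idx(y0 + 1, x0) +
      fx * fy * idx(y0 + 1, x0 + 1)
    v[!inside] <- fill
    out[, , ch] <- matrix(v, nrow = H, ncol = W)
  }
  list(raster = out, inside = matrix(inside, nrow = H, ncol = W))
}

#' Read and write landmark tables
#'
#' Landmarks are stored as CSV with columns
#' `stage,source_x,source_y,target_x,target_y`; `stage` names the
#' registration leg (e.g. `"msi_data-visium"`).
#'
#' @param path CSV file path.
#' @return `read_landmarks()` returns a tibble of landmark pairs.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stopf("landmark file not found: %s", path)
  lm <- readr::read_csv(path, show_col_types = FALSE)
  validate_landmarks(lm)
  as_tibble(lm)
}

#' @rdname read_landmarks
#' @param landmarks Data frame of landmark pairs.
#' @param stage Stage label written when the table has no `stage` column.
#' @export
write_landmarks <- function(landmarks, path, stage = "msi_data-visium") {
  lm <- as_tibble(landmarks)
  if (!"stage" %in% names(lm)) lm <- mutate(lm, stage = stage, .before = 1)
  readr::write_csv(lm, path)
  invisible(path)
}

#' Serialize a transform to JSON (and back)
#' @param transform A `spatial_transform`.
#' @param path JSON file path.
#' @export
write_transform <- function(transform, path) {
  stopifnot(inherits(transform, "spatial_transform"))
  ser <- function(t) {
    switch(t$kind,
      affine = list(kind = "affine", matrix = t$matrix,
                    domain_frame = t$domain_frame, codomain_frame = t$codomain_frame),
      tps = list(kind = "tps", control_src = t$control_src, control_dst = t$control_dst,
                 norm_center = t$norm_center, norm_scale = t$norm_scale,
                 weights = t$weights, affine_part = t$affine_part,
                 regularization = t$regularization,
                 domain_frame = t$domain_frame, codomain_frame = t$codomain_frame),
      chain = list(kind = "chain", transforms = lapply(t$transforms, ser),
                   domain_frame = t$domain_frame, codomain_frame = t$codomain_frame)
    )
  }
  jsonlite::write_json(ser(transform), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) stopf("transform file not found: %s", path)
  de <- function(o) {
    mat <- function(m) {
      m <- do.call(rbind, lapply(m, unlist))
      storage.mode(m) <- "double"
      m
    }
    switch(o$kind,
      affine = new_spatial_transform("affine", matrix = mat(o$matrix),
                                     domain_frame = o$domain_frame,
                                     codomain_frame = o$codomain_frame),
      tps = new_spatial_transform("tps",
                                  control_src = mat(o$control_src),
                                  control_dst = mat(o$control_dst),
                                  norm_center = unlist(o$norm_center),
                                  norm_scale = o$norm_scale,
                                  weights = mat(o$weights),
                                  affine_part = mat(o$affine_part),
                                  regularization = o$regularization %||% 0,
                                  domain_frame = o$domain_frame,
                                  codomain_frame = o$codomain_frame),
      chain = new_spatial_transform("chain", transforms = lapply(o$transforms, de),
                                    domain_frame = o$domain_frame,
                                    codomain_frame = o$codomain_frame)
    )
  }
  de(jsonlite::read_json(path))
}

#' @export
print.spatial_transform <- function(x, ...) {
  cat(sprintf("<spatial_transform: %s>\n", x$kind))
  if (x$kind == "affine") print(round(x$matrix, 6))
  if (x$kind == "tps") cat(sprintf("  %d control points, regularization %g\n",
                                   nrow(x$control_src), x$regularization))
  if (x$kind == "chain") cat(sprintf("  %d chained transforms\n", length(x$transforms)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a spatial transform
#'
#' For an affine transform, one row per parameter of the homogeneous matrix;
#' for a TPS, one row per control point with its weight coefficients.
#'
#' @param x A `spatial_transform`.
#' @param ... Unused.
#' @export
tidy.spatial_transform <- function(x, ...) {
  if (x$kind == "affine") {
    m <- x$matrix
    tibble(term = c("a11", "a12", "tx", "a21", "a22", "ty"),
           estimate = c(m[1, 1], m[1, 2], m[1, 3], m[2, 1], m[2, 2], m[2, 3]))
  } else if (x$kind == "tps") {
    tibble(control = seq_len(nrow(x$control_src)),
           source_x = x$control_src[, 1], source_y = x$control_src[, 2],
           target_x = x$control_dst[, 1], target_y = x$control_dst[, 2],
           weight_x = x$weights[, 1], weight_y = x$weights[, 2])
  } else {
    bind_rows(lapply(seq_along(x$transforms), function(i) {
      mutate(tidy(x$transforms[[i]]), stage = i, .before = 1)
    }))
  }
}
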