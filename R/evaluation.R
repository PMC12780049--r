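#' Alignment accuracy from tissue/background labels
#'
#' Scores a co-registration by the agreement of tissue/background labels
#' between modalities at spot level:
#' accuracy = (# spots tissue in both + # spots background in both) / # spots.
#'
#' @param visium_labels Named character vector (`"tissue"`/`"background"`),
#'   one per barcode, or a data frame with columns `barcode` and `label`.
#' @param msi_spot_labels Same shape, over the identical barcode set.
#' @param settings Optional list recorded in the report (transform kind,
#'   number of landmarks, stage, repeat index, seed).
#' @return An `alignment_report` with counts `tt`, `bb`, `tb`, `bt`,
#'   `n_spots`, and `accuracy`.
#' @export
alignment_accuracy <- function(visium_labels, msi_spot_labels, settings = list()) {
  norm <- function(l, arg) {
    if (is.data.frame(l)) l <- setNames(as.character(l$label), l$barcode)
    if (is.null(names(l))) stopf("`%s` must be named by barcode", arg)
    if (!all(l %in% c("tissue", "background"))) {
      stopf("`%s` must contain only 'tissue'/'background'", arg)
    }
    l
  }
  v <- norm(visium_labels, "visium_labels")
  m <- norm(msi_spot_labels, "msi_spot_labels")
  if (!setequal(names(v), names(m))) abort("barcode sets differ between label vectors")
  m <- m[names(v)]
  tt <- sum(v == "tissue" & m == "tissue")
  bb <- sum(v == "background" & m == "background")
  tb <- sum(v == "tissue" & m == "background")
  bt <- sum(v == "background" & m == "tissue")
  n <- length(v)
  structure(
    list(accuracy = (tt + bb) / n, n_spots = n,
         counts = c(tt = tt, bb = bb, tb = tb, bt = bt),
         settings = settings),
    class = "alignment_report"
  )
}

#' @export
print.alignment_report <- function(x, ...) {
  cat(sprintf("<alignment_report: accuracy %.4f over %d spots (tt %d, bb %d, tb %d, bt %d)>\n",
              x$accuracy, x$n_spots, x$counts["tt"], x$counts["bb"],
              x$counts["tb"], x$counts["bt"]))
  invisible(x)
}

#' @rdname alignment_accuracy
#' @param x An `alignment_report`.
#' @param ... Unused.
#' @export
glance.alignment_report <- function(x, ...) {
  tibble(accuracy = x$accuracy, n_spots = x$n_spots,
         tt = unname(x$counts["tt"]), bb = unname(x$counts["bb"]),
         tb = unname(x$counts["tb"]), bt = unname(x$counts["bt"]))
}

#' Spot-level tissue labels from assigned pixel labels
#'
#' Reduces per-pixel tissue/background labels to one label per Visium spot
#' by majority vote over the pixels assigned to that spot; ties go to
#' `"tissue"`, spots with no assigned pixels are `"background"`.
#'
#' @param mapping A [map_pixels_to_spots()] result.
#' @param pixel_labels Character vector named by pixel id, or in the order
#'   of the MSI dataset passed alongside `pixel_ids`.
#' @param pixel_ids Pixel ids for an unnamed `pixel_labels`.
#' @return Named character vector over the mapping's barcode universe.
#' @export
spot_labels_from_pixels <- function(mapping, pixel_labels, pixel_ids = NULL) {
  stopifnot(inherits(mapping, "spot_pixel_mapping"))
  if (is.null(names(pixel_labels))) {
    if (is.null(pixel_ids)) abort("pixel_labels must be named or pixel_ids supplied")
    names(pixel_labels) <- pixel_ids
  }
  a <- mapping$assignments
  lab <- pixel_labels[a$pixel_id]
  votes <- table(factor(a$barcode, levels = mapping$barcodes),
                 factor(lab, levels = c("tissue", "background")))
  out <- ifelse(votes[, "tissue"] >= votes[, "background"] & rowSums(votes) > 0,
                "tissue", "background")
  setNames(as.character(out), mapping$barcodes)
}

#' Landmark-subsampling benchmark
#'
#' Re-runs the registration with k landmarks drawn without replacement from
#' a larger pool, for every combination of k, repeat, transform kind and
#' registration stage, scoring each fit by alignment accuracy.  Each cell
#' uses a deterministic seed derived from `(seed, k, repeat)`, so any cell
#' is independently reproducible and the whole table is bit-identical
#' across runs.
#'
#' @param pool Landmark tibble (the full pool, e.g. 20 picked pairs).
#' @param k_range Integer vector of landmark counts (e.g. `4:20`).
#' @param repeats Repeats per k (draws differ by repeat).
#' @param seed Base seed.
#' @param kinds Transform kinds to test (`"affine"`, `"tps"`).
#' @param stages Stage labels to test; each is passed to `scorer`.
#' @param scorer Function `(landmarks, kind, stage)` returning an
#'   `alignment_report` (or a number).  It closes over the datasets; see
#'   the pipeline helpers for a ready-made scorer.
#' @return A tibble with class `landmark_benchmark`: columns `kind`,
#'   `stage`, `k`, `rep`, `accuracy`, `tt`, `bb`, `tb`, `bt`, `failed`.
#' @export
landmark_benchmark <- function(pool, k_range, repeats, seed, scorer,
                               kinds = c("affine", "tps"), stages = "direct") {
  validate_landmarks(pool)        # keep extra columns (e.g. intermediate-stage coords)
  pool <- as_tibble(pool)
  stopifnot(max(k_range) <= nrow(pool), repeats >= 1)
  grid <- tidyr::expand_grid(kind = kinds, stage = stages, k = as.integer(k_range),
                             rep = seq_len(repeats))
  rows <- purrr::pmap(grid, function(kind, stage, k, rep) {
    cell_seed <- derive_seed(seed, k, rep)
    idx <- withr::with_seed(cell_seed, sample.int(nrow(pool), k))
    res <- tryCatch({
      rep_out <- scorer(pool[idx, ], kind, stage)
      if (inherits(rep_out, "alignment_report")) glance(rep_out)
      else tibble(accuracy = as.numeric(rep_out), n_spots = NA_integer_,
                  tt = NA_integer_, bb = NA_integer_, tb = NA_integer_, bt = NA_integer_)
    }, error = function(e) NULL)
    if (is.null(res)) {
      tibble(kind = kind, stage = stage, k = k, rep = rep,
             accuracy = NA_real_, tt = NA_integer_, bb = NA_integer_,
             tb = NA_integer_, bt = NA_integer_, failed = TRUE)
    } else {
      tibble(kind = kind, stage = stage, k = k, rep = rep,
             accuracy = res$accuracy, tt = res$tt, bb = res$bb,
             tb = res$tb, bt = res$bt, failed = FALSE)
    }
  })
  out <- bind_rows(rows)
  class(out) <- c("landmark_benchmark", class(out))
  out
}

#' Best accuracy per condition
#' @param benchmark A [landmark_benchmark()] table.
#' @return Tibble of per-(kind, stage) maxima over all k and repeats.
#' @export
benchmark_best <- function(benchmark) {
  benchmark |>
    filter(!.data$failed) |>
    group_by(.data$kind, .data$stage) |>
    summarise(best_accuracy = max(.data$accuracy), .groups = "drop")
}

#' Accuracy-vs-landmarks plot
#'
#' Mean accuracy per number of landmarks with standard-error bars, one
#' colour per (kind, stage) condition.
#'
#' @param object A [landmark_benchmark()] table.
#' @param ... Unused.
#' @export
autoplot.landmark_benchmark <- function(object, ...) {
  df <- object |>
    filter(!.data$failed) |>
    group_by(.data$kind, .data$stage, .data$k) |>
    summarise(mean_acc = mean(.data$accuracy),
              se = stats::sd(.data$accuracy) / sqrt(n()), .groups = "drop") |>
    mutate(condition = paste(.data$kind, .data$stage, sep = " / "))
  ggplot2::ggplot(df, ggplot2::aes(.data$k, .data$mean_acc, colour = .data$condition)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_acc - .data$se,
                                        ymax = .data$mean_acc + .data$se), width = 0.3) +
    ggplot2::labs(x = "number of landmarks", y = "mean alignment accuracy",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Visium tissue/background labels from the positions table
#' @param visium A [visium_dataset()].
#' @return Named character vector (`"tissue"`/`"background"`) per barcode.
#' @export
visium_tissue_labels <- function(visium) {
  stopifnot(inherits(visium, "visium_dataset"))
  setNames(ifelse(visium$positions$in_tissue > 0, "tissue", "background"),
           visium$positions$barcode)
}

#' Build an alignment-accuracy scorer for the landmark benchmark
#'
#' Returns a closure over the paired datasets that fits the requested
#' transform on a landmark subset, projects the MSI pixels into the
#' full-resolution frame, maps them to spots and scores tissue/background
#' agreement.  With `stage = "intermediate"` and a pool carrying
#' `micro_x`/`micro_y` columns, the registration is performed in two legs
#' (data image -> microscopy image -> Visium image) and composed.
#'
#' @param visium A [visium_dataset()].
#' @param msi An [msi_dataset()] in its native frame.
#' @param pixel_labels Per-pixel `"tissue"`/`"background"` labels in MSI
#'   pixel order (e.g. from [tissue_labels_from_pc1()]).
#' @param visium_labels Optional per-barcode labels; defaults to
#'   [visium_tissue_labels()].
#' @param mode Radius convention for [map_pixels_to_spots()].
#' @param radius Optional radius override in full-resolution pixels.
#' @return Function `(landmarks, kind, stage)` -> `alignment_report`.
#' @export
make_alignment_scorer <- function(visium, msi, pixel_labels,
                                  visium_labels = NULL,
                                  mode = "expanded", radius = NULL) {
  stopifnot(inherits(visium, "visium_dataset"), inherits(msi, "msi_dataset"))
  visium_labels <- visium_labels %||% visium_tissue_labels(visium)
  radius <- radius %||% compute_spot_radius(visium, msi, mode)
  pix_lab <- setNames(pixel_labels, msi$pixels$pixel_id)
  xy <- as.matrix(msi$pixels[, c("x", "y")])
  function(landmarks, kind = "affine", stage = "direct") {
    tr <- if (identical(stage, "intermediate") &&
              all(c("micro_x", "micro_y") %in% names(landmarks))) {
      leg1 <- tibble(source_x = landmarks$source_x, source_y = landmarks$source_y,
                     target_x = landmarks$micro_x, target_y = landmarks$micro_y)
      leg2 <- tibble(source_x = landmarks$micro_x, source_y = landmarks$micro_y,
                     target_x = landmarks$target_x, target_y = landmarks$target_y)
      compose_transforms(estimate_transform(leg2, kind), estimate_transform(leg1, kind))
    } else {
      estimate_transform(landmarks, kind)
    }
    coords <- apply_transform(tr, xy)
    mapping <- map_pixels_to_spots(visium, coords, radius, mode,
                                   pixel_ids = msi$pixels$pixel_id)
    spot_labels <- spot_labels_from_pixels(mapping, pix_lab)
    alignment_accuracy(visium_labels, spot_labels,
                       settings = list(kind = kind, stage = stage,
                                       n_landmarks = nrow(landmarks)))
  }
}
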