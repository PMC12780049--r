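#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n across all_of row_number
#' @importFrom stats prcomp quantile median rnbinom rnorm runif setNames var
#' @importFrom utils head tail
NULL

# Coerce points given as a 2-column matrix, data.frame or tibble (x, y)
# into an n x 2 numeric matrix.  Used at every geometry boundary.
as_xy_matrix <- function(points, arg = "points") {
  if (is.data.frame(points)) {
    cols <- if (all(c("x", "y") %in% names(points))) c("x", "y") else names(points)[1:2]
    points <- as.matrix(points[, cols, drop = FALSE])
  }
  if (!is.matrix(points) || ncol(points) != 2) {
    abort(sprintf("`%s` must be a 2-column matrix or a data frame with x/y columns", arg))
  }
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) {
    abort(sprintf("`%s` contains non-finite coordinates", arg))
  }
  unname(points)
}

# Deterministic 32-bit sub-seed from a base seed and integer tags, so that
# individual benchmark cells are independently reproducible.
derive_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  h <- 0
  for (t in tags) h <- (h * 1103515245 + as.double(t) + 12345) %% 2147483647
  as.integer(h)
}

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))
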