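test_that("affine estimation recovers generating parameters from noiseless pairs", {
  for (seed in c(11, 23, 57)) {
    gen <- random_affine(seed)
    src <- withr::with_seed(seed + 100, matrix(runif(16, 0, 100), 8, 2))
    dst <- apply_transform(gen, src)
    lm_tbl <- tibble::tibble(source_x = src[, 1], source_y = src[, 2],
                             target_x = dst[, 1], target_y = dst[, 2])
    est <- estimate_transform(lm_tbl, "affine")
    expect_lt(max(abs(est$matrix - gen$matrix)) / max(abs(gen$matrix)), 1e-8)

    # independent oracle: per-axis ordinary least squares via lm()
    fx <- stats::lm(dst[, 1] ~ src[, 1] + src[, 2])
    fy <- stats::lm(dst[, 2] ~ src[, 1] + src[, 2])
    oracle <- rbind(c(coef(fx)[2], coef(fx)[3], coef(fx)[1]),
                    c(coef(fy)[2], coef(fy)[3], coef(fy)[1]),
                    c(0, 0, 1))
    expect_equal(est$matrix, unname(oracle), tolerance = 1e-10)
  }
})

test_that("affine fit is least squares over all pairs when landmarks are noisy", {
  gen <- random_affine(5)
  src <- withr::with_seed(6, matrix(runif(24, 0, 100), 12, 2))
  dst <- apply_transform(gen, src) + withr::with_seed(7, matrix(rnorm(24, 0, 2), 12, 2))
  est <- estimate_transform(tibble::tibble(source_x = src[, 1], source_y = src[, 2],
                                           target_x = dst[, 1], target_y = dst[, 2]),
                            "affine")
  fx <- stats::lm(dst[, 1] ~ src[, 1] + src[, 2])
  fy <- stats::lm(dst[, 2] ~ src[, 1] + src[, 2])
  expect_equal(est$matrix[1, ], unname(coef(fx))[c(2, 3, 1)], tolerance = 1e-10)
  expect_equal(est$matrix[2, ], unname(coef(fy))[c(2, 3, 1)], tolerance = 1e-10)
})

test_that("degenerate landmark configurations are rejected with informative errors", {
  col_lm <- tibble::tibble(source_x = 1:4, source_y = 2 * (1:4) + 1,
                           target_x = 1:4, target_y = 1:4)
  expect_error(estimate_transform(col_lm, "affine"), "collinear")
  few <- tibble::tibble(source_x = 1:2, source_y = c(0, 1), target_x = 1:2, target_y = c(0, 1))
  expect_error(estimate_transform(few, "affine"), "3")
  few3 <- tibble::tibble(source_x = c(0, 1, 0), source_y = c(0, 0, 1),
                         target_x = c(0, 1, 0), target_y = c(0, 0, 1))
  expect_error(estimate_transform(few3, "tps"), "4")
  dup <- tibble::tibble(source_x = c(0, 1, 0, 0), source_y = c(0, 0, 1, 0),
                        target_x = 1:4, target_y = 1:4)
  expect_error(estimate_transform(dup, "affine"), "duplicated")
})

test_that("pure translation and identity are recovered exactly", {
  src <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
  idt <- estimate_transform(tibble::tibble(source_x = src[, 1], source_y = src[, 2],
                                           target_x = src[, 1], target_y = src[, 2]),
                            "affine")
  expect_equal(idt$matrix, diag(3), tolerance = 1e-12)
  tr <- estimate_transform(tibble::tibble(source_x = src[, 1], source_y = src[, 2],
                                          target_x = src[, 1] + 10, target_y = src[, 2] + 5),
                           "affine")
  expect_equal(tr$matrix[1:2, 1:2], diag(2), tolerance = 1e-12)
  expect_equal(tr$matrix[1:2, 3], c(10, 5), tolerance = 1e-12)
})

test_that("TPS interpolates every control point and reproduces an affine map", {
  src <- withr::with_seed(9, matrix(runif(10, 0, 100), 5, 2))
  dst <- src + withr::with_seed(10, matrix(rnorm(10, 0, 5), 5, 2))
  tps <- estimate_transform(tibble::tibble(source_x = src[, 1], source_y = src[, 2],
                                           target_x = dst[, 1], target_y = dst[, 2]),
                            "tps")
  expect_lt(max(abs(apply_transform(tps, src) - dst)), 1e-6)

  # pairs sampled from an affine: TPS equals the affine on a held-out grid
  gen <- random_affine(3)
  src <- withr::with_seed(4, matrix(runif(16, 0, 100), 8, 2))
  dst <- apply_transform(gen, src)
  tps <- estimate_transform(tibble::tibble(source_x = src[, 1], source_y = src[, 2],
                                           target_x = dst[, 1], target_y = dst[, 2]),
                            "tps")
  grid <- as.matrix(expand.grid(x = seq(10, 90, length.out = 20),
                                y = seq(10, 90, length.out = 20)))
  expect_lt(max(abs(apply_transform(tps, grid) - apply_transform(gen, grid))), 1e-6)
})

test_that("apply_transform keeps tibble shape and is permutation-equivariant", {
  tr <- random_affine(8)
  pts <- withr::with_seed(12, matrix(runif(40, 0, 50), 20, 2))
  out <- apply_transform(tr, pts)
  perm <- withr::with_seed(13, sample.int(20))
  expect_equal(apply_transform(tr, pts[perm, ]), out[perm, ])

  df <- tibble::tibble(x = pts[, 1], y = pts[, 2], id = letters[1:20])
  res <- apply_transform(tr, df)
  expect_s3_class(res, "tbl_df")
  expect_equal(res$id, df$id)
  expect_equal(cbind(res$x, res$y), out)
})

test_that("composition collapses affines, chains TPS, and is associative", {
  t1 <- msialign:::new_spatial_transform("affine", matrix = rbind(c(1, 0, 1), c(0, 1, 0), c(0, 0, 1)))
  t2 <- msialign:::new_spatial_transform("affine", matrix = rbind(c(1, 0, 0), c(0, 1, 1), c(0, 0, 1)))
  comp <- compose_transforms(t1, t2)
  expect_equal(comp$matrix[1:2, 3], c(1, 1))

  a <- random_affine(1); b <- random_affine(2); cc <- random_affine(3)
  pts <- withr::with_seed(14, matrix(runif(20, 0, 10), 10, 2))
  left <- apply_transform(compose_transforms(compose_transforms(a, b), cc), pts)
  right <- apply_transform(compose_transforms(a, compose_transforms(b, cc)), pts)
  expect_lt(max(abs(left - right)), 1e-9)

  expect_equal(apply_transform(compose_transforms(a, identity_transform()), pts),
               apply_transform(a, pts))

  # chain with a TPS member applies sequentially
  src <- withr::with_seed(15, matrix(runif(12, 0, 100), 6, 2))
  dst <- apply_transform(b, src)
  tps <- estimate_transform(tibble::tibble(source_x = src[, 1], source_y = src[, 2],
                                           target_x = dst[, 1], target_y = dst[, 2]), "tps")
  chain <- compose_transforms(a, tps)
  expect_identical(chain$kind, "chain")
  expect_equal(apply_transform(chain, src), apply_transform(a, apply_transform(tps, src)),
               tolerance = 1e-9)
})

test_that("frame mismatch in composition is fatal and names both frames", {
  t1 <- estimate_transform(tibble::tibble(source_x = c(0, 1, 0, 2), source_y = c(0, 0, 1, 2),
                                          target_x = c(0, 1, 0, 2), target_y = c(0, 0, 1, 2)),
                           "affine", domain_frame = "micro", codomain_frame = "fullres")
  t2 <- estimate_transform(tibble::tibble(source_x = c(0, 1, 0, 2), source_y = c(0, 0, 1, 2),
                                          target_x = c(0, 1, 0, 2), target_y = c(0, 0, 1, 2)),
                           "affine", domain_frame = "msi_native", codomain_frame = "msi_native")
  expect_error(compose_transforms(t1, t2), "msi_native.*micro|micro.*msi_native")
})

test_that("two-stage chain with an identity intermediate equals the direct fit", {
  gen <- random_affine(21)
  src <- withr::with_seed(22, matrix(runif(20, 0, 100), 10, 2))
  dst <- apply_transform(gen, src)
  mk <- function(s, d) tibble::tibble(source_x = s[, 1], source_y = s[, 2],
                                      target_x = d[, 1], target_y = d[, 2])
  direct <- estimate_transform(mk(src, dst), "tps")
  leg1 <- estimate_transform(mk(src, src), "tps")       # identity intermediate
  leg2 <- estimate_transform(mk(src, dst), "tps")
  chained <- compose_transforms(leg2, leg1)
  grid <- as.matrix(expand.grid(seq(20, 80, 10), seq(20, 80, 10)))
  expect_lt(max(abs(apply_transform(chained, grid) - apply_transform(direct, grid))), 1e-6)
})

test_that("image warping shifts content exactly and inverts to within interpolation error", {
  img <- matrix(0, 20, 20)
  img[8:12, 5:9] <- 100
  ident <- identity_transform()
  out <- transform_image(img, ident, c(20, 20))
  expect_equal(out$raster[, , 1], img)

  shift <- msialign:::new_spatial_transform("affine",
                                            matrix = rbind(c(1, 0, 3), c(0, 1, 2), c(0, 0, 1)))
  out <- transform_image(img, shift, c(20, 20))
  expect_equal(out$raster[3:20, 4:20, 1], img[1:18, 1:17])

  # smooth image: warp then inverse-warp stays close away from borders
  smooth <- outer(1:40, 1:40, function(r, c) 100 * sin(r / 8) * cos(c / 9) + 120)
  warp <- msialign:::new_spatial_transform("affine",
    matrix = rbind(c(cos(0.1), -sin(0.1), 3), c(sin(0.1), cos(0.1), -2), c(0, 0, 1)))
  fwd <- transform_image(smooth, warp, c(40, 40))
  back <- transform_image(fwd$raster[, , 1], invert_transform(warp), c(40, 40))
  core <- 10:30
  expect_lt(mean(abs(back$raster[core, core, 1] - smooth[core, core])), 2)
})

test_that("non-invertible affine image warps are fatal", {
  sing <- msialign:::new_spatial_transform("affine",
                                           matrix = rbind(c(1, 0, 0), c(1, 0, 0), c(0, 0, 1)))
  expect_error(transform_image(matrix(1, 5, 5), sing, c(5, 5)), "invertible")
})

test_that("transform serialization round-trips affine, TPS and chains", {
  tmp <- withr::local_tempdir()
  aff <- random_affine(31)
  p1 <- file.path(tmp, "aff.json")
  write_transform(aff, p1)
  expect_equal(read_transform(p1)$matrix, aff$matrix)

  src <- withr::with_seed(32, matrix(runif(12, 0, 50), 6, 2))
  dst <- apply_transform(aff, src) + 0.5
  tps <- estimate_transform(tibble::tibble(source_x = src[, 1], source_y = src[, 2],
                                           target_x = dst[, 1], target_y = dst[, 2]), "tps")
  chain <- compose_transforms(aff, tps)
  p2 <- file.path(tmp, "chain.json")
  write_transform(chain, p2)
  pts <- withr::with_seed(33, matrix(runif(10, 0, 40), 5, 2))
  expect_equal(apply_transform(read_transform(p2), pts), apply_transform(chain, pts),
               tolerance = 1e-12)
})

test_that("landmark tables round-trip through CSV", {
  tmp <- withr::local_tempdir()
  lm <- tibble::tibble(source_x = c(0, 10, 0, 10), source_y = c(0, 0, 10, 10),
                       target_x = c(5, 15.5, 5, 15.5), target_y = c(2, 2, 12.25, 12.25))
  p <- file.path(tmp, "lm.csv")
  write_landmarks(lm, p)
  back <- read_landmarks(p)
  expect_equal(back[, names(lm)], lm)
  expect_true("stage" %in% names(back))
})
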