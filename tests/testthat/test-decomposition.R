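random_image <- function(h, w, seed = 1) {
  set.seed(seed)
  array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
}

test_that("feature matrix rows follow raster order with fixed columns", {
  img <- random_image(2, 3)
  fm <- build_feature_matrix(img, compute_index_stack(img))
  expect_identical(dim(fm), c(6L, 15L))
  expect_identical(colnames(fm)[1:3], c("R", "G", "B"))
  # row 5 (0-based row 4) is pixel (1, 1) 0-based
  expect_equal(unname(fm[5, 1:3]), as.numeric(img[2, 2, ]))
  # column G equals the row-major flattened green channel
  expect_equal(unname(fm[, "G"]), as.numeric(t(img[, , 2])))

  one <- random_image(1, 1, seed = 2)
  expect_identical(dim(build_feature_matrix(one, compute_index_stack(one))),
                   c(1L, 15L))
  expect_error(build_feature_matrix(img, compute_index_stack(one)), "disagree")
})

test_that("correlation PCA matches an independent SVD solver", {
  img <- random_image(100, 100, seed = 9)
  fm <- build_feature_matrix(img, compute_index_stack(img))
  for (block in c("rgb", "index")) {
    pcs <- pca_block(fm, block)
    cols <- if (block == "rgb") c("R", "G", "B")
            else setdiff(colnames(fm), c("R", "G", "B"))
    oracle <- stats::prcomp(fm[, cols], center = TRUE, scale. = TRUE)
    expect_equal(pcs$eigenvalues, unname(oracle$sdev^2), tolerance = 1e-8)
    # scores agree up to the sign convention
    for (k in seq_along(pcs$eigenvalues)) {
      if (pcs$eigenvalues[k] < 1e-8) next
      agree <- max(abs(pcs$scores[, k] - oracle$x[, k]))
      flip <- max(abs(pcs$scores[, k] + oracle$x[, k]))
      expect_lt(min(agree, flip), 1e-6)
    }
    # total explained variance equals the number of retained columns
    expect_equal(sum(pcs$eigenvalues), length(cols), tolerance = 1e-6)
    # loadings orthonormal, scores uncorrelated
    expect_equal(crossprod(pcs$loadings), diag(ncol(pcs$loadings)),
                 tolerance = 1e-8, ignore_attr = TRUE)
    sc <- pcs$scores[, pcs$eigenvalues > 1e-8]
    cc <- stats::cor(sc)
    expect_lt(max(abs(cc[upper.tri(cc)])), 1e-6)
  }
})

test_that("correlation PCA is scale-free and deterministic", {
  img <- random_image(40, 40, seed = 3)
  fm <- build_feature_matrix(img, compute_index_stack(img))
  pcs1 <- pca_block(fm, "index")
  fm2 <- fm
  fm2[, "ROO_G"] <- fm2[, "ROO_G"] * 1000
  pcs2 <- pca_block(fm2, "index")
  expect_equal(pcs1$scores, pcs2$scores, tolerance = 1e-9)
  # bit-stable across repeated runs (sign convention removes ambiguity)
  expect_identical(pca_block(fm, "index")$scores, pcs1$scores)
})

test_that("a rank-1 two-column block loads everything on PC1", {
  x <- cbind(R = rnorm(500), G = 0, B = 0)
  x[, "B"] <- 2 * x[, "R"]
  x[, "G"] <- rnorm(500)
  fm <- x[, c("R", "G", "B")]
  pcs <- pca_block(fm[, c("R", "B")], "all")
  expect_equal(pcs$eigenvalues[1], 2, tolerance = 1e-10)
  expect_equal(pcs$eigenvalues[2], 0)
})

test_that("constant columns are dropped with a warning; all-constant errors", {
  fm <- cbind(R = rep(1, 50), G = rnorm(50), B = rnorm(50))
  expect_warning(pcs <- pca_block(fm, "rgb"), "zero-variance")
  expect_identical(pcs$dropped, "R")
  expect_identical(ncol(pcs$scores), 2L)
  fm0 <- cbind(R = rep(1, 50), G = rep(2, 50), B = rep(0, 50))
  expect_warning(expect_error(pca_block(fm0, "rgb"), "degenerate"))
})

test_that("scale_to_gray maps linearly with round-half-up", {
  expect_identical(as.integer(scale_to_gray(matrix(c(-1, 0, 1), 1, 3))),
                   c(0L, 128L, 255L))
  expect_warning(g <- scale_to_gray(matrix(5, 2, 2)), "constant")
  expect_true(all(g == 0L))
  field <- matrix(c(0, 255, 100, 30), 2, 2)
  expect_identical(scale_to_gray(field), matrix(as.integer(field), 2, 2))
  # monotone: score order is preserved
  f <- matrix(sort(rnorm(64)), 8, 8)
  g <- scale_to_gray(f)
  expect_true(all(diff(as.numeric(g)) >= 0))
})

test_that("combine_pc blends displayed gray fields convexly", {
  a <- matrix(as.integer(seq(0, 255, length.out = 36)), 6, 6)
  b <- matrix(as.integer(rev(seq(0, 255, length.out = 36))), 6, 6)
  expect_identical(combine_pc(a, b, 0), b)
  expect_identical(combine_pc(a, b, 1), a)
  half <- combine_pc(a, b, 0.5)
  expect_identical(half, scale_to_gray(0.5 * a + 0.5 * b))
  # constant blend hits the degenerate all-zero rule
  expect_warning(
    z <- combine_pc(matrix(100L, 3, 3), matrix(200L, 3, 3), 0.5), "constant")
  expect_true(all(z == 0L))
  expect_error(combine_pc(a, b[1:3, ], 0.5), "disagree")
})
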