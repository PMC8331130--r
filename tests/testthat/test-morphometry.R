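test_that("boundary pixels match the brute-force neighbor test", {
  one <- matrix(0L, 3, 3); one[2, 2] <- 1L
  expect_identical(boundary_pixels(one),
                   cbind(row = 2L, col = 2L))

  sq <- matrix(0L, 5, 5); sq[2:4, 2:4] <- 1L
  bp <- boundary_pixels(sq)
  expect_identical(nrow(bp), 8L)   # all but the center
  expect_false(any(bp[, 1] == 3L & bp[, 2] == 3L))

  set.seed(31)
  blob <- random_mask(15, 18, 0.5)
  bp <- boundary_pixels(blob)
  oracle <- NULL
  for (i in 1:15) for (j in 1:18) {
    if (blob[i, j] == 0L) next
    isb <- FALSE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ni <- i + di; nj <- j + dj
      if (ni < 1 || ni > 15 || nj < 1 || nj > 18 || blob[ni, nj] == 0L) isb <- TRUE
    }
    if (isb) oracle <- rbind(oracle, c(i, j))
  }
  expect_identical(unname(bp[order(bp[, 1], bp[, 2]), ]), oracle)
})

test_that("length and width match exhaustive boundary-pair search", {
  run <- matrix(1L, 1, 5)
  m <- measure_length_width(run)
  expect_equal(m$length_px, 4)
  expect_equal(m$width_px, 0)

  rect <- matrix(1L, 3, 5)
  m <- measure_length_width(rect)
  oracle <- brute_length_width(boundary_pixels(rect))
  expect_equal(m$length_px, sqrt(20))
  expect_equal(m$length_px, oracle$length)
  expect_equal(m$width_px, oracle$width)

  set.seed(17)
  for (trial in 1:8) {
    blob <- disk_mask(30, 30, 15, 15, 5 + 3 * runif(1)) |
      disk_mask(30, 30, 15 + sample(3, 1), 15 + sample(5, 1), 4)
    blob <- matrix(as.integer(blob), 30, 30)
    m <- measure_length_width(blob)
    oracle <- brute_length_width(boundary_pixels(blob))
    expect_equal(m$length_px, oracle$length, label = sprintf("trial %d", trial))
    expect_equal(m$width_px, oracle$width, label = sprintf("trial %d", trial))
    expect_lte(m$width_px, m$length_px)
  }
})

test_that("a digital disk measures close to its diameter in all directions", {
  dk <- disk_mask(30, 30, 15, 15, 10)
  m <- measure_length_width(dk)
  expect_lt(abs(m$length_px - 20), 1)
  expect_lt(abs(m$width_px - m$length_px), 1)
})

test_that("measurements are robust to 90-degree rotation", {
  sc <- generate_scene(scene_spec(width = 80, height = 80, n_objects = 1,
                                  semi_axes_mean = c(14, 7), seed = 2))
  blob <- matrix(as.integer(sc$truth$labels > 0L), 80, 80)
  m1 <- measure_length_width(blob)
  m2 <- measure_length_width(t(blob)[ncol(blob):1, ])  # rotate 90 degrees
  expect_lt(abs(m1$length_px - m2$length_px), 1)
  expect_lt(abs(m1$width_px - m2$width_px), 1)
  # both bounded by the bbox diagonal + 1
  ss <- connected_components(blob)
  expect_lte(m1$length_px, ss$stats$diagonal[1] + 1)
  expect_lte(m1$width_px, m1$length_px)
})

test_that("reference scaling is exact arithmetic and linear", {
  mask <- matrix(0L, 40, 40)
  mask[5:14, 5:14] <- 1L            # 100 px reference
  mask[25:30, 25:36] <- 1L
  ss <- connected_components(mask)
  scl <- make_scale(ss, 1L, 50)
  expect_equal(scl$area_ratio, 0.5)
  expect_equal(scl$linear_ratio, sqrt(0.5))
  expect_equal(scl$area_ratio * scl$ref_area_px, scl$ref_area_mm2,
               tolerance = 1e-9)
  expect_error(make_scale(ss, 99L, 50), "no segment")
  expect_error(make_scale(ss, 1L, -2), "positive")

  meas <- measure_segments(ss)
  scaled <- apply_scale(meas, scl)
  expect_equal(scaled$area_mm2, meas$area_px * 0.5)
  expect_equal(scaled$length_mm, meas$length_px * sqrt(0.5))
  # doubling the area ratio doubles area_mm2 exactly
  scl2 <- scl; scl2$area_ratio <- scl$area_ratio * 2
  expect_equal(apply_scale(meas, scl2)$area_mm2, 2 * scaled$area_mm2)

  # 1 px reference of 1 mm^2: identity ratios
  one <- connected_components({m <- matrix(0L, 5, 5); m[3, 3] <- 1L; m})
  s1 <- make_scale(one, 1L, 1)
  expect_equal(s1$area_ratio, 1)
  expect_equal(s1$linear_ratio, 1)
})

test_that("a known-size reference disk recovers millimeter truth within 5%", {
  sc <- generate_scene(scene_spec(width = 360, height = 360, n_objects = 10,
                                  reference = list(radius = 30, area_mm2 = 285),
                                  seed = 6))
  mask <- matrix(as.integer(sc$truth$labels > 0L), 360, 360)
  ss <- segment_pipeline(mask, segment_thresholds(area_min = 10))
  meas <- measure_segments(ss)
  ref_pred <- meas$id[which.max(meas$area_px)]   # the disk dwarfs the seeds
  scl <- make_scale(ss, ref_pred, 285)
  scaled <- apply_scale(meas, scl)
  sc_score <- score_against_truth(ss, sc$truth, exclude_pred_ids = ref_pred)
  expect_identical(sc_score$count_error, 0L)
  prow <- match(sc_score$matches$pred_id, scaled$id)
  trow <- match(sc_score$matches$truth_id, sc$truth$objects$id)
  rel <- abs(scaled$length_mm[prow] - sc$truth$objects$length_mm[trow]) /
    sc$truth$objects$length_mm[trow]
  expect_lt(stats::median(rel), 0.05)
})
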