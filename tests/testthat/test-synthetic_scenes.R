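test_that("scenes are deterministic for a fixed seed", {
  sp <- scene_spec(width = 150, height = 120, n_objects = 8, n_specks = 3,
                   fraction_touching = 0.25, seed = 14)
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$labels, b$truth$labels)
  expect_identical(a$truth$objects, b$truth$objects)
})

test_that("truth bookkeeping is exact", {
  sp <- scene_spec(width = 200, height = 200, n_objects = 10,
                   fraction_touching = 0.4, seed = 3,
                   reference = list(radius = 15, area_mm2 = 70))
  sc <- generate_scene(sp)
  tr <- sc$truth
  expect_identical(tr$count, 10L)
  expect_identical(nrow(tr$objects), 10L)
  # recorded areas equal rendered pixel-set sizes
  for (i in tr$objects$id)
    expect_identical(tr$objects$area_px[tr$objects$id == i],
                     as.numeric(sum(tr$labels == i)))
  # distinct objects own disjoint pixel sets by construction
  expect_identical(sum(tr$labels > 0L),
                   as.integer(sum(tr$objects$area_px) + tr$reference$area_px +
                              sum(tr$specks$area_px)))
  # mm truth is an exact rescale of pixel truth
  lr <- sqrt(tr$reference$area_mm2 / tr$reference$area_px)
  expect_equal(tr$objects$length_mm, tr$objects$length_px * lr)
  expect_equal(tr$objects$area_mm2, tr$objects$area_px * lr^2)
})

test_that("a noiseless single ellipse equals the analytic inequality", {
  sp <- scene_spec(width = 60, height = 60, n_objects = 1, noise_sd = 0,
                   semi_axes_mean = c(12, 7), semi_axes_sd = c(0, 0), seed = 5)
  sc <- generate_scene(sp)
  o <- sc$truth$objects
  px <- brute_ellipse_pixels(60, 60, o$center_row + 1, o$center_col + 1,
                             o$semi_major, o$semi_minor, o$rotation)
  got <- which(sc$truth$labels == o$id, arr.ind = TRUE)
  expect_identical(unname(got[order(got[, 1], got[, 2]), ]), unname(px))
  # the rendered image is two-valued without noise
  expect_identical(sort(unique(as.integer(sc$image))),
                   sort(unique(c(sp$background, sp$fill_color))))
})

test_that("empty scenes and infeasible densities behave as specified", {
  sc0 <- generate_scene(scene_spec(n_objects = 0, seed = 1))
  expect_identical(sc0$truth$count, 0L)
  expect_true(all(sc0$truth$labels == 0L))
  expect_error(
    generate_scene(scene_spec(width = 60, height = 60, n_objects = 50, seed = 1)),
    "larger canvas")
})

test_that("touching pairs fuse in the mask but stay separate in truth", {
  sc <- generate_scene(scene_spec(width = 300, height = 300, n_objects = 10,
                                  fraction_touching = 1, seed = 9))
  mask <- matrix(as.integer(sc$truth$labels > 0L), 300, 300)
  cc <- connected_components(mask)
  expect_identical(segment_count(cc), 5L)   # 5 fused pairs
  expect_identical(sc$truth$count, 10L)
  expect_true(all(sc$truth$objects$touching))
})

test_that("specks stay below 20% of the smallest object", {
  sc <- generate_scene(scene_spec(width = 250, height = 250, n_objects = 8,
                                  n_specks = 5, seed = 13))
  min_obj <- min(sc$truth$objects$area_px)
  expect_true(all(sc$truth$specks$area_px < 0.2 * min_obj))
})

test_that("scoring reports perfect, missed and fused predictions", {
  sc <- generate_scene(scene_spec(width = 220, height = 220, n_objects = 6,
                                  seed = 8))
  ss <- connected_components(matrix(as.integer(sc$truth$labels > 0L), 220, 220))
  perfect <- score_against_truth(ss, sc$truth)
  expect_identical(perfect$count_error, 0L)
  expect_true(all(perfect$matches$iou == 1))

  # drop one predicted segment: one unmatched truth entry
  dropped <- kernelseg:::drop_segments(ss, 1L)
  miss <- score_against_truth(dropped, sc$truth)
  expect_identical(miss$count_error, -1L)
  expect_identical(length(miss$unmatched_truth), 1L)

  # fuse two truth objects into one prediction: 1 pred matches 2 truth at IoU < 1
  fused <- ss
  ids <- ss$stats$id[1:2]
  fused$labels[fused$labels == ids[2]] <- ids[1]
  fused$stats <- kernelseg:::segset_stats(fused$labels, max(fused$labels))
  fus <- score_against_truth(fused, sc$truth)
  expect_identical(fus$count_error, -1L)
  # the fused prediction matches one of its two truth objects at IoU < 1
  fused_match <- fus$matches$iou[fus$matches$pred_id == ids[1]]
  expect_lt(fused_match, 1)
  expect_identical(length(fus$unmatched_truth), 1L)
})
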