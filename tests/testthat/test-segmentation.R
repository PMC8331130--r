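test_that("BFS components agree with union-find on random masks", {
  set.seed(123)
  for (trial in 1:25) {
    mask <- random_mask(24, 24, runif(1, 0.2, 0.6))
    ss <- connected_components(mask)
    expect_identical(partition_signature(ss$labels),
                     partition_signature(uf_label(mask)),
                     label = sprintf("trial %d", trial))
  }
})

test_that("component ids are dense in raster order with tight boxes", {
  mask <- matrix(0L, 10, 12)
  mask[8:9, 2:3] <- 1L   # later in raster order
  mask[2, 5] <- 1L       # first
  mask[3, 6] <- 1L       # diagonal touch: same segment
  mask[5, 10] <- 1L
  ss <- connected_components(mask)
  expect_identical(ss$stats$id, c(1L, 2L, 3L))
  expect_identical(ss$stats$area, c(2L, 1L, 4L))
  expect_equal(ss$stats$diagonal[2], sqrt(2))
  expect_identical(unname(unlist(ss$stats[1, c("rmin", "cmin", "rmax", "cmax")])),
                   c(2L, 5L, 3L, 6L))
  # empty mask
  expect_identical(segment_count(connected_components(matrix(0L, 4, 4))), 0L)
})

test_that("lower-bound pruning matches a brute-force filter and is permanent", {
  set.seed(77)
  mask <- random_mask(40, 40, 0.45)
  ss <- connected_components(mask)
  t <- segment_thresholds(area_min = 5, diag_min = 4)
  pruned <- prune_lower(ss, t)
  keep <- ss$stats$area >= 5 & ss$stats$diagonal >= 4
  expect_identical(pruned$stats$id, ss$stats$id[keep])
  expect_identical(sum(pruned$labels > 0L), sum(ss$stats$area[keep]))

  expect_identical(prune_lower(ss, segment_thresholds())$stats, ss$stats)
  speck <- connected_components(disk_mask(5, 5, 3, 3, 0))
  expect_identical(segment_count(prune_lower(speck, segment_thresholds(area_min = 2))),
                   0L)
})

test_that("estimate_count divides by mean area, rounds half-up, floors at 2", {
  expect_identical(estimate_count(300, 100), 3L)
  expect_identical(estimate_count(250, 100), 3L)   # 2.5 rounds up
  expect_identical(estimate_count(120, 100), 2L)   # floor at 2
  expect_identical(estimate_count(40, 100), 2L)
  expect_error(estimate_count(100, 0), "positive")
})

test_that("watershed splits fused equal disks along the perpendicular bisector", {
  fd <- fused_disks(r = 8, sep = 14)
  one_disk <- sum(disk_mask(24, 24, 12, 12, 8))
  ch <- watershed_split(fd$mask, mean_area = one_disk, target = 2)
  expect_null(attr(ch, "note"))
  expect_identical(max(ch), 2L)
  # pixel conservation
  expect_identical(sum(ch > 0L), sum(fd$mask))
  # each child contains exactly one true disk center
  expect_true(ch[fd$cr, fd$c1] != ch[fd$cr, fd$c2])
  # disagreement with the bisector oracle confined to a 2-px band
  mid <- (fd$c1 + fd$c2) / 2
  idx <- which(ch > 0L, arr.ind = TRUE)
  lab <- ch[idx]
  left_lab <- ch[fd$cr, fd$c1]
  off_band <- abs(idx[, 2] - mid) > 2
  wrong <- (idx[, 2] < mid) != (lab == left_lab)
  expect_identical(sum(wrong & off_band), 0L)
  # exact determinism
  expect_identical(watershed_split(fd$mask, one_disk, 2), ch)
})

test_that("a single disk survives the shrinking marker search unsplit", {
  dk <- disk_mask(30, 30, 15, 15, 10)
  ch <- watershed_split(dk, mean_area = sum(dk), target = 2)
  expect_identical(attr(ch, "note"), "unsplittable")
  expect_identical(matrix(as.integer(ch), 30, 30), dk)
})

test_that("a chain of three touching disks splits into three even children", {
  h <- 30; w <- 60
  m <- disk_mask(h, w, 15, 12, 8) | disk_mask(h, w, 15, 26, 8) |
       disk_mask(h, w, 15, 40, 8)
  m <- matrix(as.integer(m), h, w)
  one <- sum(disk_mask(24, 24, 12, 12, 8))
  ch <- watershed_split(m, mean_area = one, target = 3)
  expect_identical(max(ch), 3L)
  areas <- as.integer(table(ch[ch > 0L]))
  expect_true(all(abs(areas - one) / one < 0.2))
  expect_identical(sum(ch > 0L), sum(m))
})

test_that("boundary shrinkage peels, splits and conserves pixels", {
  # 3x3 solid square: one peel leaves only the center
  sq <- matrix(0L, 5, 5); sq[2:4, 2:4] <- 1L
  b <- kernelseg:::cpp_boundary(sq)
  peel <- sq; peel[b] <- 0L
  expect_identical(which(peel == 1L), which(matrix(seq_len(25), 5, 5) == 13L))

  # two 5x5 squares joined by a 1-px bridge: split into 2 children
  bm <- matrix(0L, 7, 15)
  bm[2:6, 2:6] <- 1L; bm[2:6, 10:14] <- 1L; bm[4, 7:9] <- 1L
  ch <- shrink_boundary(bm, segment_thresholds(area_max = 25))
  expect_identical(max(ch), 2L)
  expect_identical(sum(ch > 0L), sum(bm))
  expect_true(all(ch[2:6, 2:6][bm[2:6, 2:6] == 1L] == ch[4, 2]))
  expect_true(ch[4, 2] != ch[4, 14])
  # the bridge midline divides between the two children
  expect_identical(ch[4, 7], ch[4, 2])
  expect_identical(ch[4, 9], ch[4, 14])

  # a segment already inside bounds is refused by the caller contract:
  # shrink on a compact disk reports unsplittable
  dk <- disk_mask(20, 20, 10, 10, 6)
  out <- shrink_boundary(dk, segment_thresholds(area_max = sum(dk) + 10))
  expect_identical(attr(out, "note"), "unsplittable")
})

test_that("expansion merges undersized fragments by longest shared border", {
  # three siblings: fragment 3 touches 1 over a long border, 2 over a short one
  lab <- matrix(0L, 10, 12)
  lab[2:9, 2:5] <- 1L
  lab[2:3, 6:11] <- 2L
  lab[5:9, 6:7] <- 3L   # area 10, below area_min
  t <- segment_thresholds(area_min = 11)
  merged <- expand_merge(lab, t)
  b1 <- brute_border_count(lab, 3L, 1L)
  b2 <- brute_border_count(lab, 3L, 2L)
  expect_gt(b1, b2)
  expect_true(all(merged[lab == 3L] == 1L))
  expect_identical(sum(merged == 1L), sum(lab == 1L) + sum(lab == 3L))

  # conservation when a fragment merges with its only sibling
  lab2 <- matrix(0L, 6, 10)
  lab2[2:5, 2:5] <- 1L
  lab2[3:4, 6:7] <- 2L
  m2 <- expand_merge(lab2, segment_thresholds(area_min = 10))
  expect_true(all(m2[lab2 > 0L] == 1L))

  # isolated undersized fragment with no neighbors is deleted
  lab3 <- matrix(0L, 8, 8)
  lab3[2:3, 2:3] <- 1L
  m3 <- expand_merge(lab3, segment_thresholds(area_min = 10))
  expect_true(all(m3 == 0L))
})

test_that("the pipeline equals prune+label on easy scenes and renumbers densely", {
  sc <- generate_scene(scene_spec(width = 250, height = 250, n_objects = 15,
                                  seed = 4))
  mask <- matrix(as.integer(sc$truth$labels > 0L), 250, 250)
  t <- segment_thresholds(area_min = 10)
  ss <- segment_pipeline(mask, t)
  easy <- prune_lower(connected_components(mask), t)
  expect_identical(segment_count(ss), sc$truth$count)
  expect_identical(partition_signature(ss$labels), partition_signature(easy$labels))
  expect_identical(ss$stats$id, seq_len(segment_count(ss)))
  expect_true(all(ss$stats$provenance == "initial"))
})

test_that("the pipeline splits touching pairs and respects the lower bounds", {
  sc <- generate_scene(scene_spec(width = 320, height = 320, n_objects = 20,
                                  fraction_touching = 0.4, seed = 11))
  mask <- matrix(as.integer(sc$truth$labels > 0L), 320, 320)
  singles <- sc$truth$objects$area_px[!sc$truth$objects$touching]
  t <- segment_thresholds(area_min = 0.25 * stats::median(singles),
                          area_max = 1.5 * stats::median(singles))
  ss <- segment_pipeline(mask, t)
  expect_identical(segment_count(ss), sc$truth$count)
  expect_true(any(ss$stats$provenance == "watershed-split"))
  expect_true(all(ss$stats$area >= t$area_min))
  expect_true(all(ss$stats$diagonal >= t$diag_min))
  # every above-bound survivor carries the unsplittable note
  over <- ss$stats$area > t$area_max | ss$stats$diagonal > t$diag_max
  expect_true(all(ss$stats$note[over] == "unsplittable"))
  # determinism
  expect_identical(segment_pipeline(mask, t)$labels, ss$labels)
})

test_that("raising area_min never increases the retained count", {
  sc <- generate_scene(scene_spec(width = 220, height = 220, n_objects = 12,
                                  n_specks = 6, seed = 21))
  mask <- matrix(as.integer(sc$truth$labels > 0L), 220, 220)
  mins <- c(0, 5, 20, 60, 120, 1e4)
  counts <- vapply(mins, function(am)
    segment_count(segment_pipeline(mask, segment_thresholds(area_min = am))),
    integer(1))
  expect_true(all(diff(counts) <= 0L))
  expect_identical(counts[length(counts)], 0L)
})

test_that("all-zero masks yield an empty segment set", {
  ss <- segment_pipeline(matrix(0L, 30, 30), segment_thresholds())
  expect_identical(segment_count(ss), 0L)
})
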