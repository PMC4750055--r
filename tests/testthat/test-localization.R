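test_that("thresholding is exact and nested across thresholds", {
  rm <- structure(list(labels = cbind(matrix(0L, 6, 3), matrix(1L, 6, 3)),
                       n_regions = 2L), class = "region_map")
  sm <- normalize_and_render(c(0, 10), rm)
  expect_false(any(threshold_saliency(normalize_and_render(c(0, 0), rm),
                                      0.3)))
  m <- threshold_saliency(sm, 0.3)
  expect_equal(m, sm$pixel_raster == 1)

  sc <- make_localization_fixture(seed = 31, clutter = 0.6)
  smap <- compute_saliency(sc$image)
  ths <- seq(0.1, 0.9, by = 0.1)
  counts <- vapply(ths, function(th) sum(threshold_saliency(smap, th)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  m5 <- threshold_saliency(smap, 0.5)
  m3 <- threshold_saliency(smap, 0.3)
  expect_true(all(!m5 | m3))  # m5 subset of m3

  expect_error(threshold_saliency(sm, 0), "between 0 and 1")
})

test_that("GrabCut recovers a high-contrast ellipse and is seed-deterministic", {
  sc <- ellipse_scene()
  smap <- compute_saliency(sc$image, segmentation = list(
    k = 100, smooth_sigma = 0.5, min_size = 20L))
  init <- threshold_saliency(smap, 0.3)
  ref <- grabcut_refine(sc$image, init, iters = 3, seed = 0)
  jaccard <- sum(ref & sc$mask) / sum(ref | sc$mask)
  expect_gte(jaccard, 0.9)
  expect_identical(ref, grabcut_refine(sc$image, init, iters = 3, seed = 0))

  empty <- matrix(FALSE, 64, 64)
  expect_error(grabcut_refine(sc$image, empty),
               class = "pestscout_degenerate_init")
  expect_error(grabcut_refine(sc$image, !empty),
               class = "pestscout_degenerate_init")
})

test_that("largest-component extraction follows size then row-major ties", {
  m <- matrix(FALSE, 12, 12)
  m[6:8, 6:8] <- TRUE
  b <- largest_component_box(m)
  expect_equal(unclass(b)[c("x0", "y0", "x1", "y1")],
               list(x0 = 5L, y0 = 5L, x1 = 8L, y1 = 8L))

  m[1:2, 1:2] <- TRUE  # smaller 4-pixel blob
  expect_equal(largest_component_box(m)$x0, 5L)

  # equal sizes: earlier first pixel in row-major order wins
  tie <- matrix(FALSE, 10, 10)
  tie[5:6, 7:8] <- TRUE   # first row-major pixel: row 5, col 7
  tie[6:7, 2:3] <- TRUE   # first row-major pixel: row 6, col 2
  expect_equal(largest_component_box(tie)$y0, 4L)

  expect_error(largest_component_box(matrix(FALSE, 3, 3)),
               class = "pestscout_empty_mask")
})

test_that("square extension widens, shifts inward and clamps", {
  b <- extend_to_square(bounding_box(10, 20, 30, 60), 100, 100)
  expect_equal(unclass(b)[1:4], list(x0 = 0L, y0 = 20L, x1 = 40L, y1 = 60L))

  sq <- bounding_box(4, 6, 24, 26)
  expect_equal(extend_to_square(sq, 50, 50), sq)

  b2 <- extend_to_square(bounding_box(0, 0, 20, 60), 100, 100)
  expect_equal(unclass(b2)[1:4], list(x0 = 0L, y0 = 0L, x1 = 60L, y1 = 60L))

  # side exceeding the short image dimension clamps to it
  b3 <- extend_to_square(bounding_box(10, 5, 90, 25), 100, 40)
  expect_equal(b3$y1 - b3$y0, 40L)
  expect_equal(b3$x1 - b3$x0, 40L)
  expect_true(b3$x0 >= 0 && b3$x1 <= 100)

  # random boxes: result is square and inside whenever possible
  set.seed(2)
  for (i in 1:20) {
    x0 <- sample(0:60, 1); y0 <- sample(0:60, 1)
    bb <- bounding_box(x0, y0, x0 + sample(1:30, 1), y0 + sample(1:30, 1))
    s <- extend_to_square(bb, 100, 100)
    expect_equal(s$x1 - s$x0, s$y1 - s$y0)
    expect_true(s$x0 >= 0 && s$y0 >= 0 && s$x1 <= 100 && s$y1 <= 100)
    expect_true(s$x0 <= bb$x0 && s$x1 >= bb$x1)
  }
})

test_that("crop-and-resize honours shape, passthrough and constants", {
  sc <- make_localization_fixture(128, 128, seed = 17)
  full <- crop_and_resize(sc$image, bounding_box(0, 0, 128, 128), 128)
  expect_identical(full, sc$image)

  small <- crop_and_resize(sc$image, bounding_box(10, 10, 74, 74), 256)
  expect_equal(dim(small), c(256L, 256L, 3L))

  uni <- solid_image(40, 40, c(0.25, 0.5, 0.75))
  out <- crop_and_resize(uni, bounding_box(5, 5, 25, 25), 64)
  expect_equal(unique(as.numeric(out[, , 1])), 0.25)
  expect_equal(unique(as.numeric(out[, , 3])), 0.75)
})

test_that("the correctness predicate enforces both restrictions directionally", {
  g <- bounding_box(10, 10, 110, 110)  # area 10000
  expect_true(is_correct_localization(g, g))
  expect_false(is_correct_localization(bounding_box(10, 10, 151, 110), g))
  # strictly inside with 15% smaller area: 100% of pred inside gt
  p <- bounding_box(10, 10, 95, 110)   # area 8500
  expect_true(is_correct_localization(p, g))
  # asymmetric: 81% sub-box passes forward, fails in reverse
  p2 <- bounding_box(10, 10, 100, 100)  # area 8100
  expect_true(is_correct_localization(p2, g))
  expect_false(is_correct_localization(g, p2))
  # disjoint boxes of equal area fail restriction (2)
  expect_false(is_correct_localization(bounding_box(200, 200, 300, 300), g))
})

test_that("localization falls back gracefully and is deterministic", {
  uni <- solid_image(96, 96, c(0.4, 0.5, 0.3))
  loc <- localize(uni, localization_config(crop_size = 64))
  expect_true(loc$fallback_used)
  expect_equal(unclass(loc$tight_box)[1:4],
               list(x0 = 0L, y0 = 0L, x1 = 96L, y1 = 96L))
  expect_equal(dim(loc$crop), c(64L, 64L, 3L))

  sc <- make_localization_fixture(seed = 3)
  l1 <- localize(sc$image, localization_config(crop_size = 64))
  l2 <- localize(sc$image, localization_config(crop_size = 64))
  expect_identical(l1, l2)
  expect_true(is_correct_localization(l1$tight_box, sc$gt_box))
  # square box contains the tight box
  expect_true(l1$square_box$x0 <= l1$tight_box$x0 &&
              l1$square_box$x1 >= l1$tight_box$x1)
})

test_that("suite accuracy averages the per-scene predicate", {
  scenes <- make_localization_suite(4, seed = 9, difficulty = "easy")
  cfg <- localization_config(crop_size = 64)
  acc <- localization_accuracy(scenes, cfg)
  ok <- vapply(scenes, function(sc) {
    is_correct_localization(localize(sc$image, cfg)$tight_box, sc$gt_box)
  }, logical(1))
  expect_equal(acc, mean(ok))
  expect_true(acc >= 0 && acc <= 1)
  expect_error(localization_accuracy(list()), "non-empty")
})

test_that("the threshold sweep is consistent with single evaluations", {
  scenes <- make_localization_suite(4, seed = 9, difficulty = "easy")
  cfg <- localization_config(crop_size = 64)
  curve <- accuracy_curve(scenes, thresholds = 0.3, config = cfg)
  expect_equal(nrow(curve), 1L)
  expect_equal(curve$accuracy, localization_accuracy(scenes, cfg))
  full <- accuracy_curve(scenes, config = cfg)
  expect_equal(full$threshold, seq(0.1, 0.9, by = 0.1))
  expect_true(all(full$accuracy >= 0 & full$accuracy <= 1))
  expect_error(accuracy_curve(scenes, thresholds = numeric(0)), "non-empty")
})
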