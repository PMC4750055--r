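test_that("colour quantization maps 8-bit values onto the flat palette", {
  img <- solid_image(2, 2, c(0, 0, 0))
  q <- quantize_colors(img, 10)
  expect_true(all(q$index_raster == 0L))

  img2 <- solid_image(2, 2, c(1, 1, 1))
  expect_true(all(quantize_colors(img2, 10)$index_raster == 999L))

  # mixed pixel: bins floor(v * 10 / 256)
  img3 <- array(c(200, 30, 129, 0, 0, 0, 0, 0, 0, 0, 0, 0) / 255,
                c(2, 2, 3))
  q3 <- quantize_colors(img3, 10)
  expect_equal(q3$index_raster[1, 1], 7L * 100L)
  expect_equal(q3$index_raster[2, 1], 1L * 100L)

  # palette entries are bin centres
  occ <- q$occurring
  expect_equal(unname(q$palette[1, ]), rep((0 + 0.5) * 256 / 10 / 255, 3))

  expect_error(quantize_colors(img, 1), "at least 2")
})

test_that("ten bins per channel yield exactly 1000 producible colours", {
  # enumerate every 8-bit value through the quantizer itself
  ramp <- array(rep((0:255) / 255, 3), c(16, 16, 3))
  q <- quantize_colors(ramp, 10)
  gray_idx <- sort(unique(as.integer(q$index_raster)))
  expect_length(gray_idx, 10)  # 10 bins along the gray diagonal
  # one representative 8-bit value per bin, expanded over all 3 channels
  reps <- (0:255)[!duplicated(floor((0:255) * 10 / 256))] / 255
  combos <- as.matrix(expand.grid(R = reps, G = reps, B = reps))
  img <- array(combos, c(100, 10, 3))
  idx <- quantize_colors(img, 10)$index_raster
  expect_length(unique(as.integer(idx)), 1000)
})

test_that("region histograms count quantized colours", {
  img <- two_tone_image(4, 4, left = c(0, 0, 0), right = c(1, 1, 1))
  rmap <- structure(list(labels = matrix(0L, 4, 4), n_regions = 1L),
                    class = "region_map")
  h <- build_region_histograms(quantize_colors(img, 10), rmap)
  expect_length(h, 1)
  expect_equal(sort(h[[1]]$colors), c(0L, 999L))
  expect_equal(h[[1]]$probs, c(0.5, 0.5))

  # 4 pixels {a, a, a, b}
  img2 <- solid_image(2, 2, c(0, 0, 0))
  img2[1, 1, ] <- 1
  h2 <- build_region_histograms(quantize_colors(img2, 10), rmap2 <-
    structure(list(labels = matrix(0L, 2, 2), n_regions = 1L),
              class = "region_map"))
  expect_equal(sort(h2[[1]]$probs), c(0.25, 0.75))
  expect_equal(sum(h2[[1]]$probs), 1, tolerance = 1e-9)

  big <- structure(list(labels = matrix(0L, 3, 3), n_regions = 1L),
                   class = "region_map")
  expect_error(build_region_histograms(quantize_colors(img2, 10), big),
               "raster sizes")
})

test_that("colour distances are symmetric, zero at identity, and max-scaled to 1", {
  pal <- function(i) {
    bR <- i %/% 100; bG <- (i %/% 10) %% 10; bB <- i %% 10
    c(bR + 0.5, bG + 0.5, bB + 0.5) * 256 / 10 / 255
  }
  c1 <- pal(321); c2 <- pal(765)
  expect_equal(color_distance(c1, c1), 0)
  expect_equal(color_distance(c1, c2), color_distance(c2, c1))

  # brute force over the full 1000-colour palette: the maximal CIELab pair
  # is the green/blue corner pair (not black/white), and it scales to 1
  full <- t(vapply(0:999, pal, numeric(3)))
  pts <- grDevices::convertColor(full, from = "sRGB", to = "Lab")
  D <- as.matrix(stats::dist(pts))
  mx <- which(D == max(D), arr.ind = TRUE)[1, ]
  expect_equal(sort(as.integer(mx) - 1L), c(9L, 90L))
  expect_equal(color_distance(pal(mx[1] - 1L), pal(mx[2] - 1L)), 1)
  expect_lt(color_distance(pal(0), pal(999)), 1)

  # under plain RGB the black/white extremes are a maximal pair
  expect_equal(color_distance(pal(0), pal(999), metric = "rgb"), 1)
  expect_error(color_distance(c1, c2, metric = "hsv"))
})

test_that("region colour distance is the probability-weighted double sum", {
  h <- function(colors, probs) list(region = 0L, colors = colors,
                                    probs = probs)
  a <- 0L; b <- 777L
  ha <- h(a, 1); hb <- h(b, 1)
  expect_equal(region_color_distance(ha, ha), 0)
  Dab <- color_distance(pestscout:::palette_colors(a, 10L)[1, ],
                        pestscout:::palette_colors(b, 10L)[1, ])
  expect_equal(region_color_distance(ha, hb), Dab)
  expect_equal(region_color_distance(h(c(a, b), c(0.5, 0.5)), hb),
               0.5 * Dab)
  # symmetry over random histogram pairs
  set.seed(8)
  for (i in 1:10) {
    ca <- sample(0:999, 4); cb <- sample(0:999, 3)
    pa <- runif(4); pa <- pa / sum(pa)
    pb <- runif(3); pb <- pb / sum(pb)
    expect_equal(region_color_distance(h(ca, pa), h(cb, pb)),
                 region_color_distance(h(cb, pb), h(ca, pa)),
                 tolerance = 1e-12)
  }
})

test_that("two-region saliency matches the closed form and grows with sigma_s", {
  hists <- list(list(region = 0L, colors = 0L, probs = 1),
                list(region = 1L, colors = 999L, probs = 1))
  stats <- data.frame(region = 0:1, pixel_count = c(100L, 300L),
                      cx = c(0.2, 0.2), cy = c(0.1, 0.6))  # distance 0.5
  delta <- region_color_distance(hists[[1]], hists[[2]])
  s <- region_saliency(hists, stats, saliency_config(sigma_s = 0.45))
  w <- exp(-0.5 / 0.45^2)
  expect_equal(s, c(w * 300 * delta, w * 100 * delta), tolerance = 1e-12)

  sig_grid <- c(0.2, 0.45, 0.8, 1.5)
  s1 <- vapply(sig_grid, function(sg) {
    region_saliency(hists, stats, saliency_config(sigma_s = sg))[1]
  }, numeric(1))
  expect_true(all(diff(s1) > 0))
})

test_that("optimized saliency equals the brute-force nested loop", {
  cfg <- saliency_config()
  for (seed in 1:8) {
    inst <- random_region_instance(seed, h = 40L, w = 40L,
                                   n_regions = sample(3:12, 1))
    quant <- quantize_colors(inst$image, cfg$bins_per_channel)
    hist <- build_region_histograms(quant, inst$region_map)
    st <- compute_region_stats(inst$region_map)
    expect_equal(region_saliency(hist, st, cfg),
                 brute_force_saliency(hist, st, cfg), tolerance = 1e-9)
  }
})

test_that("normalization maps to [0,1] with degenerate cases at zero", {
  rm <- structure(list(labels = cbind(matrix(0L, 4, 2), matrix(1L, 4, 2)),
                       n_regions = 2L), class = "region_map")
  sm <- normalize_and_render(c(5, 15), rm)
  expect_equal(sm$region_values, c(0, 1))
  expect_equal(unique(as.numeric(sm$pixel_raster[, 1:2])), 0)
  expect_equal(unique(as.numeric(sm$pixel_raster[, 3:4])), 1)

  expect_equal(normalize_and_render(c(3, 3), rm)$region_values, c(0, 0))
  rm1 <- structure(list(labels = matrix(0L, 2, 2), n_regions = 1L),
                   class = "region_map")
  expect_equal(normalize_and_render(7, rm1)$region_values, 0)
  expect_error(normalize_and_render(c(1, 2, 3), rm), "per region")
})

test_that("end-to-end saliency highlights the object and is deterministic", {
  uni <- solid_image(64, 64, c(0.3, 0.6, 0.2))
  expect_warning(sm0 <- compute_saliency(uni), NA)
  expect_true(all(sm0$pixel_raster == 0))

  sc <- make_localization_fixture(seed = 5)
  sm <- compute_saliency(sc$image)
  expect_true(all(sm$pixel_raster >= 0 & sm$pixel_raster <= 1))
  inside <- sm$pixel_raster[sc$mask]
  outside <- sm$pixel_raster[!sc$mask]
  expect_gt(mean(inside), mean(outside))
  expect_identical(sm, compute_saliency(sc$image))

  # a small object on a large background inherits the background's weight
  sc2 <- ellipse_scene()
  sm2 <- compute_saliency(sc2$image, segmentation = list(
    k = 100, smooth_sigma = 0.5, min_size = 20L))
  expect_equal(max(sm2$pixel_raster[sc2$mask]), 1)
})
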