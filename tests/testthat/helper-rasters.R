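# Shared in-code fixtures for the test suite.

# constant-colour RGB array
solid_image <- function(h, w, col) {
  img <- array(0, c(h, w, 3L))
  for (ch in 1:3) img[, , ch] <- col[ch]
  img
}

# left/right halves in two colours
two_tone_image <- function(h = 20L, w = 20L,
                           left = c(1, 0, 0), right = c(0, 0, 1)) {
  img <- solid_image(h, w, left)
  for (ch in 1:3) img[, (w %/% 2 + 1):w, ch] <- right[ch]
  img
}

# solid ellipse on a uniform background, with its true mask
ellipse_scene <- function(h = 64L, w = 64L, bg = c(0.4, 0.45, 0.35),
                          fg = c(0.9, 0.1, 0.1), rx = 14, ry = 9) {
  img <- solid_image(h, w, bg)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  ys <- matrix(seq_len(h) - 1L, h, w)
  xs <- matrix(seq_len(w) - 1L, h, w, byrow = TRUE)
  mask <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
  for (ch in 1:3) {
    layer <- img[, , ch]
    layer[mask] <- fg[ch]
    img[, , ch] <- layer
  }
  list(image = round(img * 255) / 255, mask = mask)
}

# random Voronoi-cell region map plus blocky random image, for oracle tests
random_region_instance <- function(seed, h = 48L, w = 48L, n_regions = 8L) {
  set.seed(seed)
  px <- runif(n_regions, 0, w - 1)
  py <- runif(n_regions, 0, h - 1)
  ys <- matrix(seq_len(h) - 1L, h, w)
  xs <- matrix(seq_len(w) - 1L, h, w, byrow = TRUE)
  lab <- matrix(0L, h, w)
  dmin <- matrix(Inf, h, w)
  for (r in seq_len(n_regions)) {
    d <- (xs - px[r])^2 + (ys - py[r])^2
    upd <- d < dmin
    lab[upd] <- r - 1L
    dmin[upd] <- d[upd]
  }
  # relabel to consecutive ids (some cells may be empty)
  ids <- sort(unique(as.integer(lab)))
  lab <- matrix(match(as.integer(lab), ids) - 1L, h, w)
  img <- array(0, c(h, w, 3L))
  cols <- matrix(runif(length(ids) * 3), ncol = 3)
  for (r in seq_along(ids)) {
    for (ch in 1:3) {
      layer <- img[, , ch]
      layer[lab == r - 1L] <- cols[r, ch] + runif(sum(lab == r - 1L), 0, 0.2)
      img[, , ch] <- layer
    }
  }
  img <- round(pmin(img, 1) * 255) / 255
  list(image = img,
       region_map = structure(list(labels = lab, n_regions = length(ids)),
                              class = "region_map"))
}

# brute-force region-contrast saliency: nested loops, no matrix algebra
brute_force_saliency <- function(histograms, stats, config) {
  n <- length(histograms)
  sapply(seq_len(n), function(k) {
    s <- 0
    for (i in seq_len(n)) {
      if (i == k) next
      ds <- sqrt((stats$cx[k] - stats$cx[i])^2 +
                 (stats$cy[k] - stats$cy[i])^2)
      dr <- region_color_distance(histograms[[k]], histograms[[i]],
                                  metric = config$color_metric,
                                  bins_per_channel = config$bins_per_channel)
      s <- s + exp(-ds / config$sigma_s^2) * stats$pixel_count[i] * dr
    }
    s
  })
}

# mean-colour separation between object and background pixels of a scene
measured_contrast <- function(scene) {
  mu_o <- apply(scene$image, 3, function(ch) mean(ch[scene$mask]))
  mu_b <- apply(scene$image, 3, function(ch) mean(ch[!scene$mask]))
  sqrt(sum((mu_o - mu_b)^2))
}
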