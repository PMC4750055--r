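# Global-contrast region-based saliency: quantize colours, build per-region
# colour histograms, and score each region by its size- and distance-weighted
# colour contrast to every other region.

#' Saliency configuration
#'
#' @param bins_per_channel number of quantization levels per RGB channel
#'   (default 10, i.e. a 10^3-colour palette).
#' @param sigma_s spatial weighting strength; the pairwise weight is
#'   `exp(-D_s / sigma_s^2)` with `D_s` the Euclidean distance between
#'   normalized region centroids. The default 0.45 is deliberately large so
#'   that contrast to far regions still contributes.
#' @param color_metric `"lab"` (Euclidean distance in CIELab, scaled so the
#'   palette-wide maximum is 1) or `"rgb"` (likewise-scaled RGB distance).
#' @return A list of class `"saliency_config"`.
#' @export
saliency_config <- function(bins_per_channel = 10L, sigma_s = 0.45,
                            color_metric = c("lab", "rgb")) {
  if (!is.numeric(bins_per_channel) || bins_per_channel < 2) {
    stop("`bins_per_channel` must be at least 2", call. = FALSE)
  }
  if (!is.numeric(sigma_s) || sigma_s <= 0) {
    stop("`sigma_s` must be positive", call. = FALSE)
  }
  color_metric <- match.arg(color_metric)
  structure(list(bins_per_channel = as.integer(bins_per_channel),
                 sigma_s = sigma_s, color_metric = color_metric),
            class = "saliency_config")
}

#' Uniform colour quantization
#'
#' Each 8-bit channel value `v` maps to bin `floor(v * bins / 256)`; the flat
#' palette index is `bR * bins^2 + bG * bins + bB`, so `bins^3` colours are
#' producible. Palette entries are bin centres `(b + 0.5) * 256 / bins` (on
#' the 0–255 scale, stored normalized to `[0, 1]`).
#'
#' @param image numeric `(H, W, 3)` RGB array in `[0, 1]` on the 8-bit grid.
#' @param bins_per_channel quantization levels per channel (>= 2).
#' @return A list of class `"color_quantization"`: `index_raster` (`H x W`
#'   integer matrix of flat indices), `bins_per_channel`, `occurring` (sorted
#'   unique indices) and `palette` (matrix of their RGB bin-centre colours).
#' @export
quantize_colors <- function(image, bins_per_channel = 10L) {
  assert_rgb(image)
  bins <- as.integer(bins_per_channel)
  if (bins < 2L) stop("`bins_per_channel` must be at least 2", call. = FALSE)
  v <- round(image * 255)
  b <- floor(v * bins / 256)
  idx <- b[, , 1] * bins^2 + b[, , 2] * bins + b[, , 3]
  occurring <- sort(unique(as.integer(idx)))
  palette <- palette_colors(occurring, bins)
  structure(list(index_raster = matrix(as.integer(idx), dim(image)[1]),
                 bins_per_channel = bins,
                 occurring = occurring, palette = palette),
            class = "color_quantization")
}

# bin-centre RGB colours (in [0,1]) of flat palette indices
palette_colors <- function(indices, bins) {
  bR <- indices %/% (bins^2)
  bG <- (indices %/% bins) %% bins
  bB <- indices %% bins
  cbind(R = (bR + 0.5) * 256 / bins,
        G = (bG + 0.5) * 256 / bins,
        B = (bB + 0.5) * 256 / bins) / 255
}

# cache of palette-wide maximum pairwise distances, keyed by bins + metric
.pestscout_cache <- new.env(parent = emptyenv())

palette_space <- function(rgb01, metric) {
  switch(metric,
    lab = grDevices::convertColor(rgb01, from = "sRGB", to = "Lab"),
    rgb = rgb01,
    stop("unknown color metric: ", metric, call. = FALSE))
}

# maximum pairwise distance over the FULL bins^3 palette (the scaling constant)
palette_max_distance <- function(bins, metric) {
  key <- paste0(metric, "_", bins)
  if (!is.null(.pestscout_cache[[key]])) return(.pestscout_cache[[key]])
  full <- palette_colors(0:(bins^3 - 1L), bins)
  pts <- palette_space(full, metric)
  # the maximum pairwise distance is attained between hull vertices; for the
  # palette sizes used here plain dist() is affordable
  mx <- max(stats::dist(pts))
  .pestscout_cache[[key]] <- mx
  mx
}

#' Distance between two quantized palette colours
#'
#' Symmetric, zero iff the colours are identical. Distances are Euclidean in
#' the chosen space and divided by the maximum pairwise distance over the full
#' palette, so the palette-wide maximum is exactly 1.
#'
#' @param c_i,c_j RGB colours in `[0, 1]` (length-3 vectors, e.g. palette
#'   rows of [quantize_colors()]).
#' @param metric `"lab"` or `"rgb"`.
#' @param bins_per_channel palette resolution used for the scaling constant.
#' @return A non-negative scalar.
#' @export
color_distance <- function(c_i, c_j, metric = c("lab", "rgb"),
                           bins_per_channel = 10L) {
  metric <- match.arg(metric)
  pts <- palette_space(rbind(c_i, c_j), metric)
  sqrt(sum((pts[1, ] - pts[2, ])^2)) /
    palette_max_distance(as.integer(bins_per_channel), metric)
}

#' Per-region colour histograms
#'
#' @param quant a [quantize_colors()] result.
#' @param region_map a [segment_graph()] result over the same raster.
#' @return A list with one element per region: `region` (0-based id),
#'   `colors` (flat palette indices occurring in the region) and `probs`
#'   (their frequencies, summing to 1).
#' @export
build_region_histograms <- function(quant, region_map) {
  if (!identical(dim(quant$index_raster), dim(region_map$labels))) {
    stop("quantization and region map have different raster sizes",
         call. = FALSE)
  }
  lab <- as.integer(region_map$labels)
  idx <- as.integer(quant$index_raster)
  lapply(0:(region_map$n_regions - 1L), function(r) {
    tab <- table(idx[lab == r])
    list(region = r,
         colors = as.integer(names(tab)),
         probs = as.numeric(tab) / sum(tab))
  })
}

#' Histogram-weighted colour distance between two regions
#'
#' The probability-weighted double sum
#' `sum_i sum_j p1(c_i) p2(c_j) D(c_i, c_j)`, which emphasises differences
#' between each region's dominant colours.
#'
#' @param h1,h2 region histograms from [build_region_histograms()].
#' @param metric `"lab"` or `"rgb"`.
#' @param bins_per_channel palette resolution.
#' @return A non-negative scalar; symmetric in its arguments.
#' @export
region_color_distance <- function(h1, h2, metric = c("lab", "rgb"),
                                  bins_per_channel = 10L) {
  metric <- match.arg(metric)
  bins <- as.integer(bins_per_channel)
  p1 <- palette_space(palette_colors(h1$colors, bins), metric)
  p2 <- palette_space(palette_colors(h2$colors, bins), metric)
  cross <- outer(rowSums(p1^2), rowSums(p2^2), "+") - 2 * p1 %*% t(p2)
  D <- sqrt(pmax(cross, 0)) / palette_max_distance(bins, metric)
  as.numeric(h1$probs %*% D %*% h2$probs)
}

#' Raw region-contrast saliency values
#'
#' Each region `r_k` is scored by its contrast to all other regions,
#' `S(r_k) = sum_{i != k} exp(-D_s(r_k, r_i) / sigma_s^2) * w(r_i) *
#' D_r(r_k, r_i)`, where `w(r_i)` is the other region's pixel count, `D_s`
#' the Euclidean distance between normalized centroids and `D_r` the
#' histogram-weighted colour distance. Large regions therefore lend their
#' weight to whatever contrasts with them, which is what makes a small
#' object on a large background salient.
#'
#' @param histograms output of [build_region_histograms()].
#' @param stats output of [compute_region_stats()], index-aligned.
#' @param config a [saliency_config()].
#' @return Numeric vector of non-negative raw saliency values, one per region.
#' @export
region_saliency <- function(histograms, stats, config = saliency_config()) {
  n <- length(histograms)
  if (n != nrow(stats)) {
    stop("histograms and stats are not index-aligned", call. = FALSE)
  }
  if (n == 1L) {
    warning("single-region image: saliency is an empty sum", call. = FALSE)
    return(0)
  }
  bins <- config$bins_per_channel
  # pairwise D_r through the palette-colour distance matrix of the colours
  # that actually occur: D_r = P D P^T with P the region x colour probability
  # matrix (sparse by construction)
  occurring <- sort(unique(unlist(lapply(histograms, `[[`, "colors"))))
  P <- matrix(0, n, length(occurring))
  for (i in seq_len(n)) {
    P[i, match(histograms[[i]]$colors, occurring)] <- histograms[[i]]$probs
  }
  pts <- palette_space(palette_colors(occurring, bins), config$color_metric)
  sq <- rowSums(pts^2)
  D <- sqrt(pmax(outer(sq, sq, "+") - 2 * pts %*% t(pts), 0)) /
    palette_max_distance(bins, config$color_metric)
  DR <- P %*% D %*% t(P)

  DS <- as.matrix(stats::dist(cbind(stats$cx, stats$cy)))
  W <- exp(-DS / config$sigma_s^2)
  contrib <- W * DR * matrix(stats$pixel_count, n, n, byrow = TRUE)
  diag(contrib) <- 0
  unname(rowSums(contrib))
}

#' Normalize region saliency and render a pixel map
#'
#' Min–max normalizes raw region values to `[0, 1]` and broadcasts them to
#' pixels by region lookup. Degenerate cases (a single region, or all raw
#' values equal) render as an all-zero map so batch pipelines proceed.
#'
#' @param raw numeric vector of raw region saliency values.
#' @param region_map the [segment_graph()] result the values belong to.
#' @return A list of class `"saliency_map"` with `region_values` and
#'   `pixel_raster` (`H x W` matrix in `[0, 1]`).
#' @export
normalize_and_render <- function(raw, region_map) {
  if (length(raw) != region_map$n_regions) {
    stop("one raw value per region is required", call. = FALSE)
  }
  rng <- range(raw)
  vals <- if (diff(rng) <= 0) rep(0, length(raw)) else (raw - rng[1]) / diff(rng)
  pix <- matrix(vals[region_map$labels + 1L], nrow(region_map$labels))
  structure(list(region_values = vals, pixel_raster = pix,
                 region_map = region_map),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("<saliency_map: %d x %d, %d regions, max %.3f>\n",
              nrow(x$pixel_raster), ncol(x$pixel_raster),
              length(x$region_values), max(x$pixel_raster)))
  invisible(x)
}

#' End-to-end saliency map of an image
#'
#' Composes [segment_graph()], [quantize_colors()],
#' [build_region_histograms()], [compute_region_stats()],
#' [region_saliency()] and [normalize_and_render()]. Deterministic: the same
#' image and configuration always give the same map.
#'
#' @param image numeric `(H, W, 3)` RGB array in `[0, 1]`.
#' @param config a [saliency_config()].
#' @param segmentation list of [segment_graph()] parameters
#'   (`k`, `smooth_sigma`, `min_size`).
#' @return A `"saliency_map"` object.
#' @export
compute_saliency <- function(image, config = saliency_config(),
                             segmentation = list(k = 300, smooth_sigma = 0.8,
                                                 min_size = 100L)) {
  assert_rgb(image)
  rmap <- segment_graph(image, k = segmentation$k,
                        smooth_sigma = segmentation$smooth_sigma,
                        min_size = segmentation$min_size)
  if (rmap$n_regions == 1L) {
    return(normalize_and_render(0, rmap))
  }
  quant <- quantize_colors(image, config$bins_per_channel)
  hist <- build_region_histograms(quant, rmap)
  stats <- compute_region_stats(rmap)
  raw <- region_saliency(hist, stats, config)
  normalize_and_render(raw, rmap)
}

#' Export a saliency map as an 8-bit grayscale PNG
#'
#' Pixel values are `round(255 * s)`.
#'
#' @param smap a `"saliency_map"`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_saliency_png <- function(smap, path) {
  png::writePNG(round(255 * smap$pixel_raster) / 255, path)
  invisible(path)
}
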