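# Graph-based over-segmentation (efficient minimum-spanning-tree merging) and
# per-region statistics feeding the saliency stage.

#' Graph-based image segmentation
#'
#' Partitions an RGB image into connected regions with the efficient
#' minimum-spanning-tree merge criterion: two components merge when the
#' connecting edge weight does not exceed the smaller of their internal
#' differences plus `k / |component|`. Edges connect 8-neighbours and are
#' weighted by Euclidean RGB distance (0–255 scale) after Gaussian
#' pre-smoothing; components smaller than `min_size` are absorbed into their
#' nearest neighbour, and labels are relabelled to consecutive 0-based ids.
#'
#' @param image numeric `(H, W, 3)` RGB array in `[0, 1]`.
#' @param k merge-scale constant on the 0–255 intensity scale; larger values
#'   yield fewer, larger regions.
#' @param smooth_sigma Gaussian pre-smoothing width in pixels.
#' @param min_size minimum region size in pixels.
#' @return A list of class `"region_map"` with `labels` (`H x W` integer
#'   matrix, values `0 .. n_regions - 1`) and `n_regions`.
#' @export
segment_graph <- function(image, k = 300, smooth_sigma = 0.8, min_size = 100L) {
  assert_rgb(image)
  if (!is.numeric(k) || k <= 0) stop("`k` must be positive", call. = FALSE)
  if (min_size < 1) stop("`min_size` must be at least 1", call. = FALSE)
  d <- dim(image)
  res <- fh_segment_cpp(as.numeric(image) * 255, d[1], d[2],
                        as.numeric(k), as.numeric(smooth_sigma),
                        as.integer(min_size))
  structure(list(labels = res$labels, n_regions = res$n_regions),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("<region_map: %d x %d, %d regions>\n",
              nrow(x$labels), ncol(x$labels), x$n_regions))
  invisible(x)
}

#' Per-region pixel counts and normalized centroids
#'
#' Centroids are means of 0-based pixel-centre coordinates, normalized per
#' axis (x by width, y by height) into `[0, 1]`.
#'
#' @param region_map a [segment_graph()] result.
#' @param height,width image dimensions; default taken from the label raster.
#' @return A data frame with one row per region: `region` (0-based id),
#'   `pixel_count`, `cx`, `cy`.
#' @export
compute_region_stats <- function(region_map,
                                 height = nrow(region_map$labels),
                                 width = ncol(region_map$labels)) {
  lab <- region_map$labels
  f <- factor(lab, levels = 0:(region_map$n_regions - 1L))
  counts <- as.integer(table(f))
  xs <- matrix(seq_len(width) - 1L, nrow(lab), ncol(lab), byrow = TRUE)
  ys <- matrix(seq_len(height) - 1L, nrow(lab), ncol(lab))
  cx <- tapply(as.numeric(xs), f, mean) / width
  cy <- tapply(as.numeric(ys), f, mean) / height
  data.frame(region = 0:(region_map$n_regions - 1L),
             pixel_count = counts,
             cx = as.numeric(cx), cy = as.numeric(cy))
}
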