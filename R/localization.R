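# From saliency map to localized square crop, plus the localization-accuracy
# evaluation protocol (two-restriction box correctness and threshold sweep).

#' Localization configuration
#'
#' @param threshold saliency threshold `th` in `(0, 1)`; 0.3 by default, the
#'   value at which the accuracy curve peaks.
#' @param grabcut_iters GrabCut refinement iterations (default 3).
#' @param crop_size output crop side in pixels (default 256).
#' @param seed integer seed forwarded to [grabcut_refine()].
#' @return A list of class `"localization_config"`.
#' @export
localization_config <- function(threshold = 0.3, grabcut_iters = 3L,
                                crop_size = 256L, seed = 0L) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (grabcut_iters < 1) stop("`grabcut_iters` must be >= 1", call. = FALSE)
  structure(list(threshold = threshold,
                 grabcut_iters = as.integer(grabcut_iters),
                 crop_size = as.integer(crop_size),
                 seed = as.integer(seed)),
            class = "localization_config")
}

#' Threshold a saliency map
#'
#' @param smap a `"saliency_map"` or a plain numeric matrix in `[0, 1]`.
#' @param th threshold in `(0, 1)`.
#' @return Logical matrix: pixels with saliency `>= th`.
#' @export
threshold_saliency <- function(smap, th) {
  if (!is.numeric(th) || th <= 0 || th >= 1) {
    stop("`th` must lie strictly between 0 and 1", call. = FALSE)
  }
  pix <- if (inherits(smap, "saliency_map")) smap$pixel_raster else smap
  pix >= th
}

#' Tight box of the largest connected foreground component
#'
#' Components are 8-connected; ties in size are broken in favour of the
#' component whose first pixel in row-major order comes first.
#'
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @return A [bounding_box()].
#' @export
largest_component_box <- function(mask) {
  if (!any(mask)) {
    stop(errorCondition("empty mask has no components",
                        class = c("pestscout_empty_mask", "error",
                                  "condition")))
  }
  cc <- cc_label8_cpp(mask)
  sizes <- cc$sizes
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    W <- ncol(mask)
    first_rm <- vapply(best, function(b) {
      idx <- which(cc$labels == b, arr.ind = TRUE)
      min((idx[, 1] - 1) * W + (idx[, 2] - 1))
    }, numeric(1))
    best <- best[which.min(first_rm)]
  }
  box_from_mask(cc$labels == best[1])
}

#' Extend a bounding box to a square
#'
#' The square side is the longer box side; the shorter axis is widened
#' symmetrically about the box centre. A square poking past an image edge is
#' shifted inward; if the side exceeds the image's short dimension the square
#' is clamped to that dimension (and then contains the centrally-cropped box).
#'
#' @param box a [bounding_box()] inside the image.
#' @param width,height image dimensions in pixels.
#' @return A [bounding_box()], square whenever the image permits.
#' @export
extend_to_square <- function(box, width, height) {
  side <- min(max(box$x1 - box$x0, box$y1 - box$y0), min(width, height))
  place <- function(lo, hi, dim) {
    start <- floor((lo + hi) / 2 - side / 2)
    min(max(start, 0), dim - side)
  }
  x0 <- place(box$x0, box$x1, width)
  y0 <- place(box$y0, box$y1, height)
  bounding_box(x0, y0, x0 + side, y0 + side)
}

#' Crop a square region and resize it
#'
#' @param image numeric `(H, W, 3)` RGB array.
#' @param square a [bounding_box()] inside the image.
#' @param size output side in pixels; bilinear interpolation (a crop already
#'   at `size` passes through pixel-identically).
#' @return A `(size, size, 3)` RGB array.
#' @export
crop_and_resize <- function(image, square, size = 256L) {
  assert_rgb(image)
  sub <- image[(square$y0 + 1):square$y1, (square$x0 + 1):square$x1, ,
               drop = FALSE]
  resize_rgb(sub, size, size)
}

#' Localize the salient object in an image
#'
#' Full pipeline: saliency map, fixed-threshold mask, GrabCut refinement,
#' largest-component tight box, square extension, fixed-size crop. If GrabCut
#' initialization is degenerate or the refined mask comes back empty, the
#' thresholded mask's largest component is used instead; if that too is
#' empty (an all-zero saliency map), the whole-image square is returned and
#' `fallback_used` is set.
#'
#' @param image numeric `(H, W, 3)` RGB array.
#' @param config a [localization_config()].
#' @param saliency a [saliency_config()].
#' @param segmentation [segment_graph()] parameters.
#' @return A list of class `"localization_result"`: `mask`, `tight_box`,
#'   `square_box`, `crop`, `fallback_used`.
#' @export
localize <- function(image, config = localization_config(),
                     saliency = saliency_config(),
                     segmentation = list(k = 300, smooth_sigma = 0.8,
                                         min_size = 100L)) {
  smap <- compute_saliency(image, saliency, segmentation)
  localize_from_saliency(image, smap, config)
}

#' Localize from a precomputed saliency map
#'
#' The work-horse behind [localize()]; useful when sweeping thresholds over
#' the same map.
#'
#' @inheritParams localize
#' @param smap a `"saliency_map"` for `image`.
#' @return A `"localization_result"`.
#' @export
localize_from_saliency <- function(image, smap,
                                   config = localization_config()) {
  H <- dim(image)[1]; W <- dim(image)[2]
  init <- threshold_saliency(smap, config$threshold)
  fallback_used <- FALSE
  refined <- NULL
  if (any(init) && !all(init)) {
    refined <- tryCatch(
      grabcut_refine(image, init, iters = config$grabcut_iters,
                     seed = config$seed),
      error = function(e) NULL)
  }
  if (is.null(refined) || !any(refined)) {
    refined <- init
    fallback_used <- TRUE
  }
  if (!any(refined)) {
    tight <- bounding_box(0L, 0L, W, H)
    fallback_used <- TRUE
  } else {
    tight <- largest_component_box(refined)
  }
  square <- extend_to_square(tight, width = W, height = H)
  crop <- crop_and_resize(image, square, config$crop_size)
  structure(list(mask = refined, tight_box = tight, square_box = square,
                 crop = crop, fallback_used = fallback_used),
            class = "localization_result")
}

#' @export
print.localization_result <- function(x, ...) {
  cat("<localization_result>\n  tight:  ")
  print(x$tight_box)
  cat("  square: ")
  print(x$square_box)
  if (x$fallback_used) cat("  (fallback used)\n")
  invisible(x)
}

#' Two-restriction localization correctness
#'
#' A predicted box is correct iff (1) its area differs from the ground-truth
#' area by less than 20% of the latter, and (2) at least 80% of the predicted
#' box's pixels lie inside the ground-truth box. The predicate is not
#' symmetric: restriction (2) is directional.
#'
#' @param pred,gt [bounding_box()] objects.
#' @return `TRUE` or `FALSE`.
#' @export
is_correct_localization <- function(pred, gt) {
  a_pred <- box_area(pred)
  a_gt <- box_area(gt)
  inter <- box_intersection_area(pred, gt)
  abs(a_pred - a_gt) < 0.2 * a_gt && inter / a_pred >= 0.8
}

#' Localization accuracy over a scene set
#'
#' @param scenes list of scenes (each with `image` and `gt_box`), e.g. from
#'   [make_localization_suite()].
#' @param config a [localization_config()].
#' @param saliency a [saliency_config()].
#' @param segmentation [segment_graph()] parameters.
#' @return Fraction of scenes whose tight box satisfies
#'   [is_correct_localization()].
#' @export
localization_accuracy <- function(scenes, config = localization_config(),
                                  saliency = saliency_config(),
                                  segmentation = list(k = 300,
                                                      smooth_sigma = 0.8,
                                                      min_size = 100L)) {
  if (length(scenes) == 0L) stop("`scenes` must be non-empty", call. = FALSE)
  ok <- vapply(scenes, function(sc) {
    loc <- localize(sc$image, config, saliency, segmentation)
    is_correct_localization(loc$tight_box, sc$gt_box)
  }, logical(1))
  mean(ok)
}

#' Localization accuracy as a function of the saliency threshold
#'
#' Evaluates [localization_accuracy()] at each threshold on the same scenes,
#' reusing one saliency map per scene.
#'
#' @param scenes list of scenes with ground-truth boxes.
#' @param thresholds numeric vector of thresholds (default the 0.1–0.9 sweep
#'   in steps of 0.1).
#' @param config a [localization_config()]; its `threshold` entry is swept.
#' @param saliency a [saliency_config()].
#' @param segmentation [segment_graph()] parameters.
#' @return A data frame with columns `threshold` and `accuracy`.
#' @export
accuracy_curve <- function(scenes, thresholds = seq(0.1, 0.9, by = 0.1),
                           config = localization_config(),
                           saliency = saliency_config(),
                           segmentation = list(k = 300, smooth_sigma = 0.8,
                                               min_size = 100L)) {
  if (length(thresholds) == 0L) {
    stop("`thresholds` must be non-empty", call. = FALSE)
  }
  if (length(scenes) == 0L) stop("`scenes` must be non-empty", call. = FALSE)
  smaps <- lapply(scenes, function(sc) {
    compute_saliency(sc$image, saliency, segmentation)
  })
  acc <- vapply(thresholds, function(th) {
    cfg <- config
    cfg$threshold <- th
    ok <- vapply(seq_along(scenes), function(i) {
      loc <- localize_from_saliency(scenes[[i]]$image, smaps[[i]], cfg)
      is_correct_localization(loc$tight_box, scenes[[i]]$gt_box)
    }, logical(1))
    mean(ok)
  }, numeric(1))
  data.frame(threshold = thresholds, accuracy = acc)
}
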