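# On-disk forms of the intermediate artefacts: region maps as 16-bit PNG with
# a JSON stats sidecar, saliency maps as 8-bit PNG plus a lossless array file,
# model checkpoints as RDS with a JSON architecture sidecar, and dataset
# manifests as JSON.

#' Write / read a region map as a 16-bit raster with a JSON sidecar
#'
#' The label raster is stored as a single-channel 16-bit TIFF (the installed
#' PNG writer is 8-bit only); the per-region statistics
#' ([compute_region_stats()]) go to `<path>.json`.
#'
#' @param region_map a [segment_graph()] result (at most 65535 regions).
#' @param path output TIFF path.
#' @return `path`, invisibly (`read_region_map` returns a `"region_map"`).
#' @export
write_region_map <- function(region_map, path) {
  if (region_map$n_regions > 65535L) {
    stop("too many regions for a 16-bit raster", call. = FALSE)
  }
  tiff::writeTIFF(region_map$labels / 65535, path, bits.per.sample = 16L)
  st <- compute_region_stats(region_map)
  jsonlite::write_json(st, paste0(path, ".json"), dataframe = "rows",
                       digits = NA)
  invisible(path)
}

#' @rdname write_region_map
#' @export
read_region_map <- function(path) {
  raw <- tiff::readTIFF(path)
  labels <- matrix(as.integer(round(raw * 65535)), nrow(raw))
  structure(list(labels = labels, n_regions = max(labels) + 1L),
            class = "region_map")
}

#' Write a saliency map losslessly
#'
#' Companion to [write_saliency_png()] (which rounds to 8 bits): stores the
#' full-precision pixel raster and region values as JSON.
#'
#' @param smap a `"saliency_map"`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_saliency_array <- function(smap, path) {
  jsonlite::write_json(list(region_values = smap$region_values,
                            pixel_raster = smap$pixel_raster),
                       path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Save / load a trained classifier
#'
#' The fit is stored in R's standard serialized form (RDS) together with a
#' human-readable JSON sidecar describing the architecture, training
#' configuration and final curves.
#'
#' @param fit a `"pest_cnn_fit"`.
#' @param path output `.rds` path; the sidecar goes to `<path>.json`.
#' @return `path` invisibly; `load_classifier` returns the fit.
#' @export
save_classifier <- function(fit, path) {
  saveRDS(fit, path)
  sidecar <- list(
    architecture = list(
      conv_layers = fit$spec$conv_layers,
      fc_layers = fit$spec$fc_layers,
      dropout_ratio = fit$spec$dropout_ratio,
      n_classes = fit$spec$n_classes,
      loss = fit$spec$loss,
      input_size = fit$spec$input_size),
    n_parameters = count_parameters(fit$spec),
    training = unclass(fit$config),
    curves = fit$curves)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       dataframe = "rows", digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  fit <- readRDS(path)
  if (!inherits(fit, "pest_cnn_fit")) {
    stop("not a saved pestscout classifier", call. = FALSE)
  }
  fit
}

#' Write a classification dataset to disk
#'
#' Images as PNG plus a JSON manifest (filename, 0-based label, split tag).
#'
#' @param dataset a `"labeled_dataset"`.
#' @param dir output directory.
#' @return The manifest data frame, invisibly.
#' @export
write_classification_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(dataset$items), function(i) {
    it <- dataset$items[[i]]
    fn <- sprintf("item_%04d_class%d.png", i, it$label)
    write_image(it$image, file.path(dir, fn))
    data.frame(filename = fn, label = it$label, split = dataset$split[i])
  })
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(list(n_classes = dataset$n_classes, items = manifest),
                       file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(manifest)
}
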