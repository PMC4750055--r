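# End-to-end orchestration: scene simulation, database construction from
# localized crops, classifier training and evaluation, with one global seed
# deriving every stage seed.

#' Pipeline configuration
#'
#' One global seed derives deterministic stage seeds by fixed offsets
#' (+100 localization scenes, +200 classification data, +300 training), so a
#' whole run is reproducible from a single knob.
#'
#' @param seed global seed.
#' @param simulate list: `n_scenes`, `difficulty`, `n_classes`,
#'   `n_per_class`, `image_size`.
#' @param saliency a [saliency_config()].
#' @param localization a [localization_config()].
#' @param architecture a preset index (1–10) or an [architecture_spec()].
#' @param training a [train_config()].
#' @param desk list controlling the desk-scale reduction applied to preset
#'   architectures: `input_size`, `width_divisor`, `fc_width`.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L,
                            simulate = list(n_scenes = 10L,
                                            difficulty = "easy",
                                            n_classes = 3L,
                                            n_per_class = 10L,
                                            image_size = 64L),
                            saliency = saliency_config(),
                            localization = localization_config(),
                            architecture = 1L,
                            training = train_config(batch_size = 16L,
                                                    epochs = 2L,
                                                    iters_per_epoch = 30L,
                                                    crop_size = 56L),
                            desk = list(input_size = 64L,
                                        width_divisor = 8L,
                                        fc_width = 64L)) {
  structure(list(seed = as.integer(seed), simulate = simulate,
                 saliency = saliency, localization = localization,
                 architecture = architecture, training = training,
                 desk = desk),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Serialization round-trips: `write_pipeline_config` followed by
#' `read_pipeline_config` reproduces the configuration.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config` returns a `"pipeline_config"`;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  plain <- lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    seed = y$seed,
    simulate = y$simulate,
    saliency = do.call(saliency_config, y$saliency),
    localization = do.call(localization_config, y$localization),
    architecture = if (is.numeric(y$architecture)) y$architecture
                   else do.call(architecture_spec, y$architecture),
    training = do.call(train_config, y$training),
    desk = y$desk)
}

#' Build a crop database from a directory of images
#'
#' Localizes every PNG in `in_dir`, writes the fixed-size square crop to
#' `out_dir`, and records a manifest (CSV and JSON) with the tight and
#' square boxes and a fallback flag per image. Images that hit the
#' whole-image fallback are flagged so they can be censored manually, and
#' unreadable files are logged, skipped and counted.
#'
#' @param in_dir directory of input PNG images.
#' @param out_dir output directory (created if needed).
#' @param config a [localization_config()].
#' @param saliency a [saliency_config()].
#' @param segmentation [segment_graph()] parameters.
#' @return The manifest data frame, invisibly; attribute `n_skipped` counts
#'   unreadable files.
#' @export
build_database <- function(in_dir, out_dir,
                           config = localization_config(),
                           saliency = saliency_config(),
                           segmentation = list(k = 300, smooth_sigma = 0.8,
                                               min_size = 100L)) {
  files <- sort(list.files(in_dir, pattern = "\\.png$", ignore.case = TRUE))
  if (length(files) == 0L) {
    stop("no PNG images found in ", in_dir, call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  skipped <- 0L
  for (fn in files) {
    img <- tryCatch(read_image(file.path(in_dir, fn)), error = function(e) {
      message("skipping unreadable file: ", fn)
      NULL
    })
    if (is.null(img)) {
      skipped <- skipped + 1L
      next
    }
    loc <- localize(img, config, saliency, segmentation)
    out_name <- sub("\\.png$", "_crop.png", fn, ignore.case = TRUE)
    write_image(loc$crop, file.path(out_dir, out_name))
    tb <- loc$tight_box; sb <- loc$square_box
    rows[[length(rows) + 1L]] <- data.frame(
      source = fn, crop = out_name,
      tight_x0 = tb$x0, tight_y0 = tb$y0, tight_x1 = tb$x1, tight_y1 = tb$y1,
      square_x0 = sb$x0, square_y0 = sb$y0, square_x1 = sb$x1,
      square_y1 = sb$y1, fallback = loc$fallback_used)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(images = manifest, n_skipped = skipped),
                       file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  attr(manifest, "n_skipped") <- skipped
  invisible(manifest)
}

#' Run the full pipeline on synthetic data
#'
#' Simulates a localization suite, builds the crop database, measures
#' localization accuracy, simulates a labelled classification dataset,
#' trains the classifier and evaluates it, returning one consolidated
#' report. With a `dir`, the intermediate artefacts (scenes, crops,
#' manifest, report JSON) are written there.
#'
#' @param config a [pipeline_config()].
#' @param dir optional output directory for artefacts.
#' @return A list of class `"pipeline_report"` with sections
#'   `localization`, `training` and `evaluation`.
#' @export
run_pipeline <- function(config = pipeline_config(), dir = NULL) {
  sim <- config$simulate
  scenes <- make_localization_suite(sim$n_scenes,
                                    seed = config$seed + 100L,
                                    difficulty = sim$difficulty)
  loc_acc <- localization_accuracy(scenes, config$localization,
                                   config$saliency)
  fallbacks <- 0L
  if (!is.null(dir)) {
    scene_dir <- file.path(dir, "scenes")
    write_localization_suite(scenes, scene_dir)
    manifest <- build_database(scene_dir, file.path(dir, "crops"),
                               config$localization, config$saliency)
    fallbacks <- sum(manifest$fallback)
  }
  dataset <- make_classification_dataset(sim$n_classes, sim$n_per_class,
                                         image_size = sim$image_size,
                                         seed = config$seed + 200L)
  spec <- if (inherits(config$architecture, "architecture_spec")) {
    config$architecture
  } else {
    desk_scale(architecture_preset(config$architecture),
               input_size = sim$image_size,
               width_divisor = config$desk$width_divisor,
               fc_width = config$desk$fc_width,
               n_classes = sim$n_classes)
  }
  tcfg <- config$training
  tcfg$seed <- config$seed + 300L
  fit <- train_classifier(spec, dataset, tcfg)
  report <- evaluate_classifier(fit, dataset)
  out <- structure(list(
    localization = list(n_scenes = sim$n_scenes,
                        difficulty = sim$difficulty,
                        accuracy = loc_acc, n_fallbacks = fallbacks,
                        threshold = config$localization$threshold),
    training = list(curves = fit$curves,
                    n_parameters = count_parameters(spec)),
    evaluation = list(accuracy = report$accuracy, map = report$map,
                      per_class = report$per_class),
    seed = config$seed), class = "pipeline_report")
  if (!is.null(dir)) {
    jsonlite::write_json(
      rapply(unclass(out), function(x) x, how = "replace"),
      file.path(dir, "report.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  localization: %.3f accuracy on %d %s scenes (th=%.2f)\n",
              x$localization$accuracy, x$localization$n_scenes,
              x$localization$difficulty, x$localization$threshold))
  cat(sprintf("  classifier:   %.3f accuracy, %.3f mAP\n",
              x$evaluation$accuracy, x$evaluation$map))
  invisible(x)
}
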