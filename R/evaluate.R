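# Classifier evaluation: accuracy, per-class precision/recall, one-vs-rest
# average precision and mAP, plus the architecture ablation table.

#' Evaluate a classifier on a labelled dataset
#'
#' Accuracy is the fraction correct under argmax. Per-class average precision
#' is the area under the one-vs-rest precision–recall curve obtained by
#' ranking all items by the class score; mAP is the mean over classes. A
#' class absent from the data has undefined AP: it is flagged with a warning
#' and excluded from the mean. Because ranked mAP and plain mean per-class
#' precision are both in use as summary figures, the report carries both
#' (`map` is the ranked quantity).
#'
#' @param model a `"pest_cnn_fit"`.
#' @param dataset a `"labeled_dataset"`.
#' @param split which split tags to use (default `"val"`; use `"all"` for
#'   every item).
#' @return A list of class `"eval_report"`: `accuracy`, `per_class` (data
#'   frame with precision/recall/AP), `map`, `mean_precision`,
#'   `undefined_classes`.
#' @export
evaluate_classifier <- function(model, dataset, split = "val") {
  items <- dataset$items
  keep <- if (identical(split, "all")) {
    seq_along(items)
  } else {
    which(dataset$split %in% split)
  }
  if (length(keep) == 0L) stop("no items in the requested split",
                               call. = FALSE)
  labels <- vapply(items[keep], `[[`, integer(1), "label")
  sub <- structure(list(items = items[keep], n_classes = dataset$n_classes,
                        split = dataset$split[keep]),
                   class = "labeled_dataset")
  scores <- predict(model, sub, type = "scores")
  pred <- max.col(scores, ties.method = "first") - 1L
  acc <- mean(pred == labels)
  K <- dataset$n_classes
  per <- data.frame(class = 0:(K - 1L), n = NA_integer_,
                    precision = NA_real_, recall = NA_real_, ap = NA_real_)
  for (k in 0:(K - 1L)) {
    pos <- labels == k
    per$n[k + 1L] <- sum(pos)
    tp <- sum(pred == k & pos)
    per$precision[k + 1L] <- if (sum(pred == k) > 0) tp / sum(pred == k)
                             else NA_real_
    per$recall[k + 1L] <- if (sum(pos) > 0) tp / sum(pos) else NA_real_
    if (sum(pos) > 0) {
      ord <- order(scores[, k + 1L], decreasing = TRUE)
      hits <- pos[ord]
      prec_at <- cumsum(hits) / seq_along(hits)
      per$ap[k + 1L] <- sum(prec_at[hits]) / sum(hits)
    }
  }
  undefined <- per$class[is.na(per$ap)]
  if (length(undefined)) {
    warning("AP undefined for absent class(es): ",
            paste(undefined, collapse = ", "), call. = FALSE)
  }
  structure(list(accuracy = acc, per_class = per,
                 map = mean(per$ap, na.rm = TRUE),
                 mean_precision = mean(per$precision, na.rm = TRUE),
                 undefined_classes = undefined),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: accuracy %.3f, mAP %.3f>\n", x$accuracy, x$map))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Architecture ablation table
#'
#' Trains each requested preset (reduced to desk scale so the runs finish on
#' a workstation) on the same dataset with deterministic per-row seeds and
#' tabulates the full-scale parameter count next to the validation accuracy.
#'
#' @param presets integer vector of preset indices (1–10).
#' @param dataset a `"labeled_dataset"`.
#' @param config a [train_config()]; row seeds are `config$seed + type`.
#' @param input_size,width_divisor,fc_width desk-scale reduction applied to
#'   each preset before training (see [desk_scale()]).
#' @return A data frame with columns `type`, `n_parameters`,
#'   `val_accuracy`.
#' @export
ablation_table <- function(presets, dataset, config = train_config(),
                           input_size = dim(dataset$items[[1]]$image)[1],
                           width_divisor = 8L, fc_width = 64L) {
  if (length(presets) < 1L) stop("need at least one preset", call. = FALSE)
  rows <- lapply(presets, function(tp) {
    full <- architecture_preset(tp)
    spec <- desk_scale(full, input_size = input_size,
                       width_divisor = width_divisor, fc_width = fc_width,
                       n_classes = dataset$n_classes)
    cfg <- config
    cfg$seed <- config$seed + as.integer(tp)
    fit <- train_classifier(spec, dataset, cfg)
    rep <- evaluate_classifier(fit, dataset)
    data.frame(type = tp, n_parameters = count_parameters(full),
               val_accuracy = rep$accuracy)
  })
  do.call(rbind, rows)
}
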