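# Stochastic-gradient training of the convolutional classifier, exposed in
# the classic R modelling idiom: `train_classifier()` returns a classed fit
# with print/summary/predict/plot methods.

#' Training configuration
#'
#' Defaults follow the reference training recipe: mini-batches of 128,
#' initial learning rate 0.01 divided by 10 at each epoch boundary, momentum
#' 0.8, L2 weight decay 0.005, Gaussian init with sd 0.01, 3 epochs, and 5
#' random 227-pixel crops per image plus horizontal mirrors. At desk scale
#' `iters_per_epoch` is overridden downward from its full-scale default of
#' 20000.
#'
#' @param batch_size mini-batch size.
#' @param lr0 initial learning rate.
#' @param lr_decay_factor factor the learning rate is divided by at each
#'   epoch boundary.
#' @param momentum classical momentum coefficient.
#' @param weight_decay L2 penalty coefficient.
#' @param epochs number of epochs.
#' @param iters_per_epoch SGD iterations per epoch.
#' @param init_std weight initialisation standard deviation (for
#'   `init = "gaussian"`).
#' @param init `"gaussian"` or `"he"`; see [build_network()]. The desk-scale
#'   profile uses `"he"`.
#' @param input_scale factor mapping `[0, 1]` image values to network input
#'   units before mean-centring; 255 reproduces the raw 8-bit convention,
#'   1 gives normalized inputs (used at desk scale alongside `"he"` init).
#' @param seed integer seed controlling initialisation, batch sampling,
#'   cropping and dropout.
#' @param crops_per_image random crop positions per image.
#' @param crop_size crop side in pixels; set it to the image size to disable
#'   cropping.
#' @param mirror augment with horizontal mirrors.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(batch_size = 128L, lr0 = 0.01,
                         lr_decay_factor = 10, momentum = 0.8,
                         weight_decay = 0.005, epochs = 3L,
                         iters_per_epoch = 20000L, init_std = 0.01,
                         init = c("gaussian", "he"), input_scale = 255,
                         seed = 1L, crops_per_image = 5L, crop_size = 227L,
                         mirror = TRUE) {
  init <- match.arg(init)
  vals <- list(batch_size = as.integer(batch_size), lr0 = lr0,
               lr_decay_factor = lr_decay_factor, momentum = momentum,
               weight_decay = weight_decay, epochs = as.integer(epochs),
               iters_per_epoch = as.integer(iters_per_epoch),
               init_std = init_std, init = init, input_scale = input_scale,
               seed = as.integer(seed),
               crops_per_image = as.integer(crops_per_image),
               crop_size = as.integer(crop_size), mirror = isTRUE(mirror))
  for (nm in c("batch_size", "epochs", "iters_per_epoch", "crops_per_image",
               "crop_size")) {
    if (vals[[nm]] < 1) stop("`", nm, "` must be positive", call. = FALSE)
  }
  if (vals$lr0 < 0 || vals$weight_decay < 0 || vals$momentum < 0) {
    stop("rates must be non-negative", call. = FALSE)
  }
  structure(vals, class = "train_config")
}

# images on the centred network input scale
prep_input <- function(image, mean_rgb, scale = 255) {
  x <- image * scale
  for (ch in 1:3) x[, , ch] <- x[, , ch] - mean_rgb[ch]
  x
}

#' Train the convolutional classifier
#'
#' Stochastic gradient descent with classical momentum and L2 weight decay;
#' the learning rate is divided by `lr_decay_factor` at every epoch
#' boundary. Inputs are mapped to a centred 0–255 scale using the training
#' split's mean colour. Training is deterministic for a fixed config seed:
#' re-running reproduces the same weights and curves.
#'
#' @param spec an [architecture_spec()] whose `input_size` matches the
#'   dataset images and `n_classes` the dataset classes.
#' @param dataset a [make_classification_dataset()]-style
#'   `"labeled_dataset"`.
#' @param config a [train_config()].
#' @return An object of class `"pest_cnn_fit"` with elements `net`, `spec`,
#'   `config`, `mean_rgb` and `curves` (per-epoch training loss/error and
#'   validation error).
#' @export
train_classifier <- function(spec, dataset, config = train_config()) {
  if (!inherits(dataset, "labeled_dataset") || length(dataset$items) == 0L) {
    stop("`dataset` must be a non-empty labeled_dataset", call. = FALSE)
  }
  if (dataset$n_classes != spec$n_classes) {
    stop("dataset classes do not match the architecture", call. = FALSE)
  }
  tr_idx <- which(dataset$split == "train")
  va_idx <- which(dataset$split == "val")
  if (length(tr_idx) == 0L) stop("no training items", call. = FALSE)
  imgs <- lapply(dataset$items, `[[`, "image")
  labels <- vapply(dataset$items, `[[`, integer(1), "label")
  d1 <- dim(imgs[[1]])
  if (config$crop_size > min(d1[1], d1[2])) {
    stop("`crop_size` exceeds the image size", call. = FALSE)
  }
  mean_rgb <- config$input_scale * rowMeans(vapply(imgs[tr_idx],
                                                   function(im) {
    apply(im, 3, mean)
  }, numeric(3)))
  xs <- lapply(imgs, prep_input, mean_rgb = mean_rgb,
               scale = config$input_scale)

  net <- build_network(spec, seed = config$seed, init_std = config$init_std,
                       init = config$init)
  lfun <- loss_fn(spec$loss)
  vel <- lapply(net$layers, function(ly) {
    list(W = array(0, dim(ly$W)), b = rep(0, length(ly$b)))
  })
  do_crop <- config$crop_size < min(d1[1], d1[2])
  curves <- data.frame(epoch = integer(0), lr = numeric(0),
                       train_loss = numeric(0), train_error = numeric(0),
                       val_error = numeric(0))
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      lr <- config$lr0 / config$lr_decay_factor^(epoch - 1L)
      ep_loss <- 0; ep_n <- 0L; ep_correct <- 0L
      for (it in seq_len(config$iters_per_epoch)) {
        batch <- sample(tr_idx, min(config$batch_size, length(tr_idx)),
                        replace = length(tr_idx) < config$batch_size)
        acc <- NULL
        for (bi in batch) {
          x <- xs[[bi]]
          if (do_crop) {
            r0 <- sample.int(d1[1] - config$crop_size + 1L, 1L)
            c0 <- sample.int(d1[2] - config$crop_size + 1L, 1L)
            x <- x[r0:(r0 + config$crop_size - 1L),
                   c0:(c0 + config$crop_size - 1L), , drop = FALSE]
          }
          if (config$mirror && stats::runif(1) < 0.5) {
            x <- mirror_horizontal(x)
          }
          fw <- cnn_forward(net, x, train = TRUE, keep_cache = TRUE)
          ls <- lfun(fw$scores, labels[bi])
          ep_loss <- ep_loss + ls$loss
          ep_correct <- ep_correct +
            (which.max(fw$scores) == labels[bi] + 1L)
          ep_n <- ep_n + 1L
          gr <- cnn_backward(net, fw$cache, ls$grad)
          if (is.null(acc)) {
            acc <- gr
          } else {
            for (li in seq_along(gr)) {
              acc[[li]]$W <- acc[[li]]$W + gr[[li]]$W
              acc[[li]]$b <- acc[[li]]$b + gr[[li]]$b
            }
          }
        }
        nb <- length(batch)
        for (li in seq_along(net$layers)) {
          gW <- acc[[li]]$W / nb + config$weight_decay * net$layers[[li]]$W
          gb <- acc[[li]]$b / nb
          vel[[li]]$W <- config$momentum * vel[[li]]$W - lr * gW
          vel[[li]]$b <- config$momentum * vel[[li]]$b - lr * gb
          net$layers[[li]]$W <- net$layers[[li]]$W + vel[[li]]$W
          net$layers[[li]]$b <- net$layers[[li]]$b + vel[[li]]$b
        }
      }
      val_err <- if (length(va_idx)) {
        pred <- vapply(va_idx, function(i) {
          which.max(cnn_forward(net, center_crop(xs[[i]],
                                                 config$crop_size))$scores)
        }, integer(1))
        mean(pred != labels[va_idx] + 1L)
      } else NA_real_
      curves <- rbind(curves, data.frame(
        epoch = epoch, lr = lr, train_loss = ep_loss / ep_n,
        train_error = 1 - ep_correct / ep_n, val_error = val_err))
    }
  })
  structure(list(net = net, spec = spec, config = config,
                 mean_rgb = mean_rgb, curves = curves,
                 n_train = length(tr_idx), n_val = length(va_idx)),
            class = "pest_cnn_fit")
}

# evaluation-time view: single centre crop
center_crop <- function(x, size) {
  d <- dim(x)
  if (size >= d[1] && size >= d[2]) return(x)
  r0 <- (d[1] - size) %/% 2L + 1L
  c0 <- (d[2] - size) %/% 2L + 1L
  x[r0:(r0 + size - 1L), c0:(c0 + size - 1L), , drop = FALSE]
}

#' @export
print.pest_cnn_fit <- function(x, ...) {
  cat(sprintf("<pest_cnn_fit: %d classes, %s parameters, %d epoch(s)>\n",
              x$spec$n_classes,
              format(count_parameters(x$spec), big.mark = ","),
              nrow(x$curves)))
  last <- x$curves[nrow(x$curves), ]
  cat(sprintf("  final train error %.3f, val error %s\n", last$train_error,
              ifelse(is.na(last$val_error), "n/a",
                     sprintf("%.3f", last$val_error))))
  invisible(x)
}

#' @export
summary.pest_cnn_fit <- function(object, ...) {
  print(object)
  cat("\nTraining curves:\n")
  print(object$curves, row.names = FALSE)
  invisible(object$curves)
}

#' Predict classes or scores for new images
#'
#' Images are preprocessed with the fit's training mean and evaluated on a
#' single centre crop (no test-time augmentation).
#'
#' @param object a `"pest_cnn_fit"`.
#' @param newdata a `"labeled_dataset"` or list of `(H, W, 3)` arrays.
#' @param type `"class"` for 0-based argmax labels, `"scores"` for the raw
#'   score matrix (one row per image).
#' @param ... unused.
#' @return Integer vector of labels or a numeric score matrix.
#' @export
predict.pest_cnn_fit <- function(object, newdata,
                                 type = c("class", "scores"), ...) {
  type <- match.arg(type)
  imgs <- if (inherits(newdata, "labeled_dataset")) {
    lapply(newdata$items, `[[`, "image")
  } else if (is.list(newdata)) newdata else list(newdata)
  scores <- t(vapply(imgs, function(im) {
    x <- center_crop(prep_input(im, object$mean_rgb,
                                object$config$input_scale),
                     object$config$crop_size)
    cnn_forward(object$net, x)$scores
  }, numeric(object$spec$n_classes)))
  if (type == "scores") return(scores)
  max.col(scores, ties.method = "first") - 1L
}

#' Plot training and validation curves
#'
#' @param x a `"pest_cnn_fit"`.
#' @param ... forwarded to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.pest_cnn_fit <- function(x, ...) {
  cv <- x$curves
  graphics::matplot(cv$epoch, cbind(cv$train_error, cv$val_error),
                    type = "b", pch = c(1, 2), lty = 1,
                    xlab = "epoch", ylab = "error",
                    main = "classifier learning curves", ...)
  graphics::legend("topright", c("train", "validation"), pch = c(1, 2),
                   col = 1:2, lty = 1)
  invisible(x)
}
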