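# Declarative AlexNet-family architecture descriptions: the full 8-layer
# reference network, its layer-removal and width-reduction presets, parameter
# counting, and a documented desk-scale reduction.

conv_layer <- function(n_filters, kernel, stride = 1L, pad = 0L,
                       pool_after = 0L) {
  list(n_filters = as.integer(n_filters), kernel = as.integer(kernel),
       stride = as.integer(stride), pad = as.integer(pad),
       pool_after = as.integer(pool_after))
}

#' Declarative network architecture
#'
#' @param conv_layers list of convolutional layer descriptions, each a list
#'   with `n_filters`, `kernel`, `stride`, `pad`, `pool_after` (number of
#'   3x3 stride-2 max-pooling stages applied after the layer; the pooling
#'   stages are part of the fixed scaffold, so layer-removal variants stack
#'   the orphaned pools onto the last remaining conv layer).
#' @param fc_layers integer vector of hidden fully-connected widths (possibly
#'   empty); the classification layer with `n_classes` outputs is always
#'   appended.
#' @param dropout_ratio probability of deactivating a unit after each hidden
#'   FC layer during training; must be `< 1`.
#' @param n_classes number of output classes (>= 2).
#' @param loss `"softmax"` or `"hinge_ova"`.
#' @param input_size square input side in pixels.
#' @return A list of class `"architecture_spec"`.
#' @export
architecture_spec <- function(conv_layers, fc_layers = integer(0),
                              dropout_ratio = 0.7, n_classes = 12L,
                              loss = c("softmax", "hinge_ova"),
                              input_size = 227L) {
  loss <- match.arg(loss)
  if (length(conv_layers) < 1L) {
    stop("at least one convolutional layer is required", call. = FALSE)
  }
  if (n_classes < 2) stop("`n_classes` must be at least 2", call. = FALSE)
  if (dropout_ratio < 0 || dropout_ratio >= 1) {
    stop("`dropout_ratio` must lie in [0, 1); 1 would deactivate every unit",
         call. = FALSE)
  }
  structure(list(conv_layers = conv_layers,
                 fc_layers = as.integer(fc_layers),
                 dropout_ratio = dropout_ratio,
                 n_classes = as.integer(n_classes), loss = loss,
                 input_size = as.integer(input_size)),
            class = "architecture_spec")
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("<architecture_spec: input %dx%dx3, %d conv, %d fc, %d classes, %s loss, dr=%.2f>\n",
              x$input_size, x$input_size, length(x$conv_layers),
              length(x$fc_layers), x$n_classes, x$loss, x$dropout_ratio))
  for (i in seq_along(x$conv_layers)) {
    cl <- x$conv_layers[[i]]
    cat(sprintf("  Conv%d: %d filters %dx%d s%d p%d%s\n", i, cl$n_filters,
                cl$kernel, cl$kernel, cl$stride, cl$pad,
                if (cl$pool_after > 0)
                  paste0(" + ", cl$pool_after, " pool") else ""))
  }
  if (length(x$fc_layers)) {
    cat("  FC:", paste(x$fc_layers, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Architecture presets (Types 1–10)
#'
#' Type 1 is the full reference network: Conv1 with 128 filters of 11x11 and
#' stride 3 (+pool), Conv2 256@5x5 (+pool), Conv3 384@3x3, Conv4 384@3x3,
#' Conv5 256@3x3 (+pool), two 4096-unit FC layers, a 12-way output, dropout
#' 0.7 and softmax loss. Types 2–7 successively remove layers (FC7; FC6–7;
#' then Conv5, Conv4–5, Conv3–5, Conv2–5 as well); the three pooling stages
#' belong to the fixed scaffold, so pools orphaned by a removal stack onto
#' the last remaining conv layer and the classifier input stays compact. Types
#' 8–10 keep the depth but set the Conv2–5 widths to (192, 320, 320, 192),
#' (128, 256, 256, 128) and (64, 192, 192, 64).
#'
#' @param type_index integer 1–10.
#' @return An [architecture_spec()].
#' @export
architecture_preset <- function(type_index) {
  if (!is.numeric(type_index) || length(type_index) != 1L ||
      !(type_index %in% 1:10)) {
    stop("`type_index` must be a single integer in 1..10", call. = FALSE)
  }
  conv_full <- function(w2 = 256L, w3 = 384L, w4 = 384L, w5 = 256L) {
    list(conv_layer(128L, 11L, stride = 3L, pad = 0L, pool_after = 1L),
         conv_layer(w2, 5L, stride = 1L, pad = 2L, pool_after = 1L),
         conv_layer(w3, 3L, stride = 1L, pad = 1L),
         conv_layer(w4, 3L, stride = 1L, pad = 1L),
         conv_layer(w5, 3L, stride = 1L, pad = 1L, pool_after = 1L))
  }
  fc <- c(4096L, 4096L)
  convs <- conv_full()
  if (type_index == 2) fc <- 4096L
  if (type_index >= 3) fc <- integer(0)
  if (type_index %in% 4:7) {
    keep <- 5L - (type_index - 3L)  # 4 -> Conv1..4, ..., 7 -> Conv1
    n_pools <- sum(vapply(convs, `[[`, integer(1), "pool_after"))
    kept_pools <- sum(vapply(convs[seq_len(keep)], `[[`, integer(1),
                             "pool_after"))
    convs <- convs[seq_len(keep)]
    # all three pooling stages stay; orphans stack on the last conv layer
    convs[[keep]]$pool_after <- convs[[keep]]$pool_after +
      (n_pools - kept_pools)
  }
  if (type_index == 8) convs <- conv_full(192L, 320L, 320L, 192L)
  if (type_index == 9) convs <- conv_full(128L, 256L, 256L, 128L)
  if (type_index == 10) convs <- conv_full(64L, 192L, 192L, 64L)
  if (type_index %in% 8:10) fc <- c(4096L, 4096L)
  architecture_spec(convs, fc, dropout_ratio = 0.7, n_classes = 12L,
                    loss = "softmax", input_size = 227L)
}

# spatial side of the final feature map; errors on underflow
conv_geometry <- function(spec) {
  s <- spec$input_size
  ch <- 3L
  for (i in seq_along(spec$conv_layers)) {
    cl <- spec$conv_layers[[i]]
    if (cl$kernel > s + 2 * cl$pad) {
      stop(errorCondition(
        sprintf("Conv%d kernel (%d) exceeds its %dx%d input map", i,
                cl$kernel, s, s),
        class = c("pestscout_invalid_architecture", "error", "condition")))
    }
    s <- (s + 2L * cl$pad - cl$kernel) %/% cl$stride + 1L
    for (p in seq_len(cl$pool_after)) {
      if (s < 3L) {
        stop(errorCondition(
          sprintf("pool after Conv%d needs a map of side >= 3, got %d", i, s),
          class = c("pestscout_invalid_architecture", "error", "condition")))
      }
      s <- (s - 3L) %/% 2L + 1L
    }
    ch <- cl$n_filters
  }
  list(flat = s * s * ch, side = s, channels = ch)
}

#' Exact trainable parameter count of an architecture
#'
#' Weights plus biases, layer by layer: a conv layer with `F` filters of
#' `k x k x C_in` contributes `F * k^2 * C_in + F`; FC layers contribute
#' `in * out + out`, with the first FC fed by the flattened final feature
#' map and the classification layer always included.
#'
#' @param spec an [architecture_spec()].
#' @return Integer-valued numeric count.
#' @export
count_parameters <- function(spec) {
  total <- 0
  ch <- 3L
  for (cl in spec$conv_layers) {
    total <- total + cl$n_filters * (cl$kernel^2 * ch) + cl$n_filters
    ch <- cl$n_filters
  }
  geom <- conv_geometry(spec)
  widths <- c(geom$flat, spec$fc_layers, spec$n_classes)
  for (i in seq_len(length(widths) - 1L)) {
    total <- total + widths[i] * widths[i + 1L] + widths[i + 1L]
  }
  total
}

#' Desk-scale reduction of an architecture
#'
#' Shrinks an architecture for small synthetic tasks while preserving its
#' shape: the input side is reduced, every conv width divided by
#' `width_divisor`, and all hidden FC layers set to `fc_width`.
#'
#' @param spec an [architecture_spec()].
#' @param input_size reduced input side (default 64).
#' @param width_divisor divisor applied to conv filter counts (default 4).
#' @param fc_width width of each retained hidden FC layer (default 256).
#' @param n_classes optionally change the class count.
#' @return An [architecture_spec()].
#' @export
desk_scale <- function(spec, input_size = 64L, width_divisor = 4L,
                       fc_width = 256L, n_classes = spec$n_classes) {
  convs <- lapply(spec$conv_layers, function(cl) {
    cl$n_filters <- max(8L, cl$n_filters %/% as.integer(width_divisor))
    cl
  })
  architecture_spec(convs,
                    rep(as.integer(fc_width), length(spec$fc_layers)),
                    dropout_ratio = spec$dropout_ratio,
                    n_classes = n_classes, loss = spec$loss,
                    input_size = as.integer(input_size))
}
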