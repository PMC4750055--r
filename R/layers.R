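# Forward/backward primitives for the convolutional classifier. Convolutions
# run as matrix products over im2col patch matrices (C++), pooling and the
# im2col adjoint are C++; everything else is base R matrix algebra.

#' Build an initialized network from an architecture
#'
#' Weights are drawn i.i.d. from a zero-mean Gaussian with standard deviation
#' `init_std`; biases start at 0. Every convolutional and hidden FC layer is
#' followed by a ReLU; `pool_after` 3x3 stride-2 max-pooling stages follow
#' each conv layer; inverted dropout with the spec's ratio follows each hidden
#' FC layer during training.
#'
#' @param spec an [architecture_spec()].
#' @param seed integer seed; identical seeds give identical initial weights.
#' @param init_std weight initialisation standard deviation for
#'   `init = "gaussian"` (default 0.01).
#' @param init `"gaussian"` (fixed-sd, the full-scale default) or `"he"`
#'   (fan-in-scaled, `sd = sqrt(2 / fan_in)`; the desk-scale profile uses
#'   this so signal survives the reduced widths).
#' @return A list of class `"pest_cnn"` with the spec and per-layer weights.
#' @export
build_network <- function(spec, seed = 1L, init_std = 0.01,
                          init = c("gaussian", "he")) {
  init <- match.arg(init)
  geom <- conv_geometry(spec)  # validates spatial dimensions
  sd_for <- function(fan) if (init == "he") sqrt(2 / fan) else init_std
  with_seed(seed, {
    layers <- list()
    ch <- 3L
    for (i in seq_along(spec$conv_layers)) {
      cl <- spec$conv_layers[[i]]
      fan <- cl$kernel^2 * ch
      layers[[length(layers) + 1L]] <- list(
        type = "conv",
        W = matrix(stats::rnorm(fan * cl$n_filters, 0, sd_for(fan)), fan,
                   cl$n_filters),
        b = rep(0, cl$n_filters),
        kernel = cl$kernel, stride = cl$stride, pad = cl$pad,
        pool_after = cl$pool_after)
      ch <- cl$n_filters
    }
    widths <- c(geom$flat, spec$fc_layers, spec$n_classes)
    for (i in seq_len(length(widths) - 1L)) {
      layers[[length(layers) + 1L]] <- list(
        type = "fc",
        W = matrix(stats::rnorm(widths[i] * widths[i + 1L], 0,
                                sd_for(widths[i])),
                   widths[i], widths[i + 1L]),
        b = rep(0, widths[i + 1L]),
        hidden = i < length(widths) - 1L)
      }
    structure(list(spec = spec, layers = layers), class = "pest_cnn")
  })
}

#' @export
print.pest_cnn <- function(x, ...) {
  cat(sprintf("<pest_cnn: %d layers, %s parameters>\n", length(x$layers),
              format(count_parameters(x$spec), big.mark = ",")))
  invisible(x)
}

# Forward pass on one (H, W, 3) input. In training mode, inverted dropout
# masks (already scaled by 1/(1-dr)) are sampled from the current RNG stream.
# Returns scores and, if `keep_cache`, the per-layer cache for backprop.
cnn_forward <- function(net, x, train = FALSE, keep_cache = FALSE) {
  dr <- net$spec$dropout_ratio
  cache <- list()
  for (li in seq_along(net$layers)) {
    ly <- net$layers[[li]]
    st <- list()
    if (ly$type == "conv") {
      d <- dim(x)
      cols <- im2col_cpp(x, d[1], d[2], d[3], ly$kernel, ly$stride, ly$pad)
      OH <- (d[1] + 2 * ly$pad - ly$kernel) %/% ly$stride + 1L
      OW <- (d[2] + 2 * ly$pad - ly$kernel) %/% ly$stride + 1L
      z <- crossprod(cols, ly$W)
      z <- sweep(z, 2L, ly$b, "+")
      a <- array(pmax(z, 0), c(OH, OW, ncol(ly$W)))
      st <- list(in_dim = d, cols = if (keep_cache) cols,
                 pre = if (keep_cache) array(z, c(OH, OW, ncol(ly$W))))
      st$pre_dim <- c(OH, OW, ncol(ly$W))
      st$pools <- list()
      for (p in seq_len(ly$pool_after)) {
        pd <- dim(a)
        pl <- maxpool_fwd_cpp(a, pd[1], pd[2], pd[3], 3L, 2L)
        st$pools[[p]] <- list(in_dim = pd, argmax = pl$argmax)
        a <- pl$out
      }
      x <- a
    } else {
      v <- as.numeric(x)
      st$in_dim <- dim(x)
      st$input <- if (keep_cache) v
      z <- drop(crossprod(ly$W, v)) + ly$b
      if (ly$hidden) {
        a <- pmax(z, 0)
        st$pre <- if (keep_cache) z
        if (train && dr > 0) {
          mask <- (stats::runif(length(a)) >= dr) / (1 - dr)
          a <- a * mask
          st$drop_mask <- if (keep_cache) mask
        }
        x <- a
      } else {
        x <- z  # classification layer: raw scores
      }
    }
    cache[[li]] <- st
  }
  list(scores = as.numeric(x), cache = if (keep_cache) cache)
}

# Backward pass: gradient of the loss wrt every weight and bias given the
# score gradient. Returns list of per-layer list(W, b) gradients.
cnn_backward <- function(net, cache, grad_scores) {
  grads <- vector("list", length(net$layers))
  g <- grad_scores
  for (li in rev(seq_along(net$layers))) {
    ly <- net$layers[[li]]
    st <- cache[[li]]
    if (ly$type == "fc") {
      if (ly$hidden) {
        if (!is.null(st$drop_mask)) g <- g * st$drop_mask
        g <- g * (st$pre > 0)
      }
      grads[[li]] <- list(W = outer(st$input, g), b = g)
      g <- drop(ly$W %*% g)
      if (!is.null(st$in_dim)) dim(g) <- st$in_dim
    } else {
      d <- st$in_dim
      OHW <- st$pre_dim[1:2]
      nf <- ncol(ly$W)
      for (p in rev(seq_along(st$pools))) {
        pid <- st$pools[[p]]$in_dim
        g <- maxpool_bwd_cpp(as.numeric(g), st$pools[[p]]$argmax,
                             pid[1], pid[2], pid[3])
      }
      g <- as.numeric(g) * (as.numeric(st$pre) > 0)
      gm <- matrix(g, OHW[1] * OHW[2], nf)
      grads[[li]] <- list(W = st$cols %*% gm, b = colSums(gm))
      gcols <- ly$W %*% t(gm)
      g <- col2im_cpp(gcols, d[1], d[2], d[3], ly$kernel, ly$stride, ly$pad)
    }
  }
  grads
}

#' Random training crops of an image
#'
#' Draws `n` uniformly positioned square crops; with `mirror`, each crop is
#' paired with its horizontal flip, giving `2 n` views.
#'
#' @param image numeric `(H, W, 3)` array.
#' @param n number of crop positions.
#' @param size crop side in pixels; must not exceed either image dimension.
#' @param mirror also return horizontally mirrored copies.
#' @param seed integer seed.
#' @return A list of `(size, size, 3)` arrays.
#' @export
random_crops <- function(image, n = 5L, size = 227L, mirror = TRUE,
                         seed = 1L) {
  assert_rgb(image)
  d <- dim(image)
  if (size > d[1] || size > d[2]) {
    stop("crop size exceeds the image dimensions", call. = FALSE)
  }
  with_seed(seed, {
    out <- list()
    for (i in seq_len(n)) {
      r0 <- sample.int(d[1] - size + 1L, 1L)
      c0 <- sample.int(d[2] - size + 1L, 1L)
      crop <- image[r0:(r0 + size - 1L), c0:(c0 + size - 1L), , drop = FALSE]
      out[[length(out) + 1L]] <- crop
      if (mirror) out[[length(out) + 1L]] <- mirror_horizontal(crop)
    }
    out
  })
}

#' Mirror an image horizontally
#'
#' @param image numeric `(H, W, 3)` array.
#' @return The left–right flipped array; applying it twice restores the input.
#' @export
mirror_horizontal <- function(image) {
  image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
}
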