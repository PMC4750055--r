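# Seeded synthetic-scene generators. Localization fixtures emulate field
# photographs in which a single insect occupies a compact, highly colour-
# contrasting region on a muted, cluttered vegetation background; the
# classification generator produces small labelled shape/hue datasets.

hsv_to_rgb <- function(h, s, v) {
  as.numeric(grDevices::col2rgb(grDevices::hsv(h %% 1, s, v))) / 255
}

# coarse value-noise field in [-1, 1], bilinearly upsampled
noise_field <- function(height, width, cells) {
  g <- matrix(stats::runif(cells * cells, -1, 1), cells, cells)
  m <- EBImage::resize(g, w = width, h = height)
  t(m)[seq_len(height), seq_len(width), drop = FALSE]
}

# muted textured background with optional soft distractor blobs
make_scene_background <- function(height, width, clutter, blur) {
  base <- hsv_to_rgb(stats::runif(1, 0.18, 0.36), stats::runif(1, 0.2, 0.4),
                     stats::runif(1, 0.35, 0.5))
  tex <- 0.22 * noise_field(height, width, 6L) +
         0.10 * noise_field(height, width, 14L)
  bg <- array(0, c(height, width, 3L))
  for (ch in 1:3) {
    bg[, , ch] <- base[ch] * (1 + tex) +
      0.02 * noise_field(height, width, max(8L, width %/% 6L))
  }
  n_blobs <- round(clutter * 7)
  if (n_blobs > 0) {
    ys <- matrix(seq_len(height) - 1L, height, width)
    xs <- matrix(seq_len(width) - 1L, height, width, byrow = TRUE)
    for (b in seq_len(n_blobs)) {
      cx <- stats::runif(1, 0, width - 1)
      cy <- stats::runif(1, 0, height - 1)
      r <- stats::runif(1, 0.07, 0.10 + 0.12 * clutter) * min(height, width)
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      mag <- 0.15 + 0.75 * clutter
      col <- pmin(pmax(base + mag * dir, 0), 1)
      # flat-top profile: out-of-focus highlights keep a solid core
      alpha <- exp(-(((xs - cx)^2 + (ys - cy)^2) / r^2)^2)
      for (ch in 1:3) bg[, , ch] <- (1 - alpha) * bg[, , ch] + alpha * col[ch]
    }
  }
  bg <- pmin(pmax(bg, 0), 1)
  if (blur > 0) bg <- blur_rgb(bg, blur)
  bg
}

# binary mask of a rotated ellipse plus thin line appendages; returns the mask
# and the number of appendages drawn
draw_insect_mask <- function(height, width, cx, cy, rx, ry, theta) {
  ys <- matrix(seq_len(height) - 1L, height, width)
  xs <- matrix(seq_len(width) - 1L, height, width, byrow = TRUE)
  dx <- xs - cx; dy <- ys - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  mask <- (u / rx)^2 + (v / ry)^2 <= 1
  n_app <- sample(2:6, 1L)
  smax <- max(rx, ry)
  for (a in seq_len(n_app)) {
    phi <- stats::runif(1, 0, 2 * pi)
    bx <- rx * cos(phi); by <- ry * sin(phi)
    sx <- cx + bx * cos(theta) - by * sin(theta)
    sy <- cy + bx * sin(theta) + by * cos(theta)
    d <- c(sx - cx, sy - cy)
    d <- d / sqrt(sum(d^2))
    ang <- atan2(d[2], d[1]) + stats::runif(1, -0.4, 0.4)
    len <- stats::runif(1, 0.5, 1.1) * smax
    thick <- sample(1:2, 1L)
    for (s in seq(0, len, by = 0.35)) {
      px <- round(sx + s * cos(ang)); py <- round(sy + s * sin(ang))
      for (ox in 0:(thick - 1L)) for (oy in 0:(thick - 1L)) {
        r <- py + oy + 1L; c <- px + ox + 1L
        if (r >= 1L && r <= height && c >= 1L && c <= width) mask[r, c] <- TRUE
      }
    }
  }
  list(mask = mask, n_appendages = n_app)
}

#' Generate one synthetic localization scene
#'
#' Renders a single "insect" — a filled, rotated ellipse with 2–6 thin line
#' appendages — whose colour is displaced from the background mean by at least
#' `contrast` (Euclidean distance in normalized RGB), on a muted value-noise
#' texture with optional soft distractor blobs. Ground truth is the tight
#' bounding box of the rendered object mask, so all object pixels lie inside
#' it by construction.
#'
#' @param height,width image size in pixels; both must be at least 64 and the
#'   aspect ratio at most 8.
#' @param contrast target object/background mean-colour separation in `(0, 1]`,
#'   measured as Euclidean distance in normalized RGB.
#' @param clutter distractor level in `[0, 1]`: scales the number and colour
#'   strength of blurred background blobs.
#' @param seed integer seed; the same arguments and seed reproduce the scene
#'   byte for byte.
#' @param blur Gaussian blur sigma (pixels) applied to the background before
#'   the object is composited; large values emulate background bokeh.
#' @return A list of class `"synthetic_scene"` with elements `image`
#'   (`(H, W, 3)` array on the 8-bit grid), `gt_box` (a [bounding_box()]),
#'   `mask` (logical object mask) and `params` (generation record).
#' @export
make_localization_fixture <- function(height = 96L, width = 96L,
                                      contrast = 0.9, clutter = 0.2,
                                      seed = 1L, blur = 1) {
  height <- as.integer(height); width <- as.integer(width)
  if (height < 64L || width < 64L) {
    stop("scene dimensions must be at least 64 pixels", call. = FALSE)
  }
  if (max(height, width) / min(height, width) > 8) {
    stop("aspect ratios above 8 are not supported", call. = FALSE)
  }
  if (!is.numeric(contrast) || contrast <= 0 || contrast > 1) {
    stop("`contrast` must lie in (0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    bg <- make_scene_background(height, width, clutter, blur)

    # ellipse geometry: log-uniform aspect, area fraction then capped so the
    # worst-case appendage reach keeps the box inside the frame and below
    # half the image area
    q <- exp(stats::runif(1, log(0.4), log(2.5)))
    f <- stats::runif(1, 0.015, 0.05)
    rx <- sqrt(f * height * width * q / pi)
    ry <- rx / q
    cap <- min(0.15 * sqrt(height * width), 0.2 * min(height, width))
    s <- max(rx, ry)
    if (s > cap) { rx <- rx * cap / s; ry <- ry * cap / s }
    ry <- max(ry, 0.012 * height * width / (pi * rx))
    theta <- sample(c(0, pi / 2), 1L) + stats::runif(1, -0.3, 0.3)

    reach <- 2.1 * max(rx, ry) + 2
    cx <- stats::runif(1, reach, width - 1 - reach)
    cy <- stats::runif(1, reach, height - 1 - reach)
    obj <- draw_insect_mask(height, width, cx, cy, rx, ry, theta)

    # object colour: push from the background mean toward the farthest RGB
    # cube corner, overshooting the requested contrast by 15% so that the
    # measured separation survives texture noise
    mu <- apply(bg, 3, mean)
    corners <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
    dists <- sqrt(rowSums((corners - matrix(mu, 8, 3, byrow = TRUE))^2))
    corner <- corners[which.max(dists), ]
    dmax <- max(dists)
    u <- (corner - mu) / dmax
    obj_col <- mu + min(1.15 * contrast, dmax) * u

    img <- bg
    mottle <- 0.03 * noise_field(height, width, 10L)
    for (ch in 1:3) {
      layer <- img[, , ch]
      layer[obj$mask] <- pmin(pmax(obj_col[ch] * (1 + mottle[obj$mask]), 0), 1)
      img[, , ch] <- layer
    }
    img <- img_quantize8(img)
    gt_box <- box_from_mask(obj$mask)

    structure(list(
      image = img,
      gt_box = gt_box,
      mask = obj$mask,
      params = list(height = height, width = width, contrast = contrast,
                    clutter = clutter, blur = blur, seed = as.integer(seed),
                    object_color = obj_col, scale_fraction = pi * rx * ry /
                      (height * width), n_appendages = obj$n_appendages,
                    theta = theta)
    ), class = "synthetic_scene")
  })
}

#' Generate a suite of localization scenes
#'
#' Per-scene seeds are derived deterministically as `seed + index`, so scenes
#' are independent but the whole suite is reproducible from one seed. The
#' `"easy"` preset uses high contrast and light clutter; the `"hard"` preset
#' lowers contrast and adds strong, heavily blurred distractor blobs — the
#' bokeh-like background failure mode of saliency-based localization.
#'
#' @param n number of scenes (>= 1).
#' @param seed suite seed.
#' @param difficulty `"easy"` or `"hard"`.
#' @param height,width scene size in pixels.
#' @return A list of [make_localization_fixture()] scenes.
#' @export
make_localization_suite <- function(n, seed = 1L,
                                    difficulty = c("easy", "hard"),
                                    height = 96L, width = 96L) {
  if (!is.numeric(n) || n < 1) stop("`n` must be at least 1", call. = FALSE)
  difficulty <- match.arg(difficulty)
  pars <- switch(difficulty,
    easy = list(contrast = 0.9, clutter = 0.15, blur = 1),
    hard = list(contrast = 0.5, clutter = 1, blur = 2))
  lapply(seq_len(n), function(i) {
    make_localization_fixture(height = height, width = width,
                              contrast = pars$contrast,
                              clutter = pars$clutter,
                              seed = as.integer(seed) + i, blur = pars$blur)
  })
}

shape_mask <- function(shape, height, width, cx, cy, s, theta, aspect) {
  ys <- matrix(seq_len(height) - 1L, height, width)
  xs <- matrix(seq_len(width) - 1L, height, width, byrow = TRUE)
  dx <- xs - cx; dy <- ys - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  a <- s; b <- s / aspect
  switch(shape,
    ellipse = (u / a)^2 + (v / b)^2 <= 1,
    rectangle = abs(u) <= a & abs(v) <= b,
    triangle = v >= -b & (abs(u) / a + (v + b) / (2 * b)) <= 1,
    cross = (abs(u) <= a & abs(v) <= b / 2) | (abs(v) <= a & abs(u) <= b / 2),
    annulus = {
      r2 <- (u / a)^2 + (v / a)^2
      r2 <= 1 & r2 >= 0.35
    },
    diamond = abs(u) / a + abs(v) / b <= 1,
    stop("unknown shape: ", shape, call. = FALSE))
}

#' Generate a labelled synthetic classification dataset
#'
#' Each class is a distinct (shape family, hue band) combination rendered with
#' random position, scale and rotation jitter on a muted textured background.
#' Items carry 0-based integer labels and a disjoint train/val split tag.
#'
#' @param n_classes number of classes, between 2 and 12.
#' @param n_per_class images per class (>= 2).
#' @param image_size square image side in pixels.
#' @param seed integer seed.
#' @param val_fraction fraction of each class tagged `"val"` (at least one
#'   item per class in each split).
#' @return A list of class `"labeled_dataset"` with elements `items` (list of
#'   `list(image, label)`), `n_classes` and `split` (character vector aligned
#'   with `items`).
#' @export
make_classification_dataset <- function(n_classes, n_per_class,
                                        image_size = 64L, seed = 1L,
                                        val_fraction = 0.2) {
  if (!is.numeric(n_classes) || n_classes < 2 || n_classes > 12) {
    stop("`n_classes` must be between 2 and 12", call. = FALSE)
  }
  if (!is.numeric(n_per_class) || n_per_class < 2) {
    stop("`n_per_class` must be at least 2", call. = FALSE)
  }
  image_size <- as.integer(image_size)
  shapes <- rep(c("ellipse", "rectangle", "triangle",
                  "cross", "annulus", "diamond"), length.out = n_classes)
  hues <- (seq_len(n_classes) - 1) / n_classes
  items <- list()
  split <- character(0)
  n_val <- max(1L, round(val_fraction * n_per_class))
  n_val <- min(n_val, n_per_class - 1L)
  for (k in seq_len(n_classes)) {
    for (j in seq_len(n_per_class)) {
      img <- with_seed(as.integer(seed) + 1000L * k + j, {
        bg <- make_scene_background(image_size, image_size,
                                    clutter = 0.1, blur = 0.6)
        s <- stats::runif(1, 0.24, 0.36) * image_size
        cx <- (image_size - 1) / 2 + stats::runif(1, -0.08, 0.08) * image_size
        cy <- (image_size - 1) / 2 + stats::runif(1, -0.08, 0.08) * image_size
        theta <- stats::runif(1, 0, 2 * pi)
        aspect <- exp(stats::runif(1, log(1), log(1.8)))
        m <- shape_mask(shapes[k], image_size, image_size,
                        cx, cy, s, theta, aspect)
        col <- hsv_to_rgb(hues[k] + stats::runif(1, -0.02, 0.02), 0.8,
                          stats::runif(1, 0.65, 0.9))
        for (ch in 1:3) {
          layer <- bg[, , ch]
          layer[m] <- col[ch]
          bg[, , ch] <- layer
        }
        img_quantize8(bg)
      })
      items[[length(items) + 1L]] <- list(image = img, label = k - 1L)
      split <- c(split, if (j <= n_per_class - n_val) "train" else "val")
    }
  }
  structure(list(items = items, n_classes = as.integer(n_classes),
                 split = split),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset: %d items, %d classes (%d train / %d val)>\n",
              length(x$items), x$n_classes,
              sum(x$split == "train"), sum(x$split == "val")))
  invisible(x)
}

#' Write a localization suite to disk
#'
#' Writes each scene as a PNG plus annotations in CSV
#' (`filename,x0,y0,x1,y1`, 0-based half-open) and an equivalent JSON form.
#'
#' @param scenes list of scenes from [make_localization_suite()].
#' @param dir output directory (created if needed).
#' @return The annotation data frame, invisibly.
#' @export
write_localization_suite <- function(scenes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(scenes), function(i) {
    fn <- sprintf("scene_%03d.png", i)
    write_image(scenes[[i]]$image, file.path(dir, fn))
    b <- scenes[[i]]$gt_box
    data.frame(filename = fn, x0 = b$x0, y0 = b$y0, x1 = b$x1, y1 = b$y1)
  })
  ann <- do.call(rbind, rows)
  utils::write.csv(ann, file.path(dir, "boxes.csv"), row.names = FALSE)
  jsonlite::write_json(ann, file.path(dir, "boxes.json"), dataframe = "rows")
  invisible(ann)
}

#' Read box annotations from CSV or JSON
#'
#' @param path a `boxes.csv` or `boxes.json` file written by
#'   [write_localization_suite()].
#' @return A data frame with columns `filename, x0, y0, x1, y1`.
#' @export
read_annotations <- function(path) {
  if (grepl("\\.json$", path)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}
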