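#' Axis-aligned bounding box
#'
#' Boxes are 0-based and half-open: the box covers pixel columns
#' `x0 .. x1 - 1` and rows `y0 .. y1 - 1`. This makes area arithmetic exact:
#' `area = (x1 - x0) * (y1 - y0)`.
#'
#' @param x0,y0 inclusive top-left corner (0-based).
#' @param x1,y1 exclusive bottom-right corner.
#' @return An object of class `"bounding_box"`.
#' @export
bounding_box <- function(x0, y0, x1, y1) {
  x0 <- as.integer(x0); y0 <- as.integer(y0)
  x1 <- as.integer(x1); y1 <- as.integer(y1)
  if (x0 >= x1 || y0 >= y1) {
    stop("degenerate box: need x0 < x1 and y0 < y1", call. = FALSE)
  }
  structure(list(x0 = x0, y0 = y0, x1 = x1, y1 = y1), class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<box [%d,%d) x [%d,%d), %d x %d px>\n",
              x$x0, x$x1, x$y0, x$y1, x$x1 - x$x0, x$y1 - x$y0))
  invisible(x)
}

box_area <- function(box) {
  (box$x1 - box$x0) * (box$y1 - box$y0)
}

box_intersection_area <- function(a, b) {
  w <- min(a$x1, b$x1) - max(a$x0, b$x0)
  h <- min(a$y1, b$y1) - max(a$y0, b$y0)
  if (w <= 0 || h <= 0) return(0L)
  w * h
}

# tight box of the TRUE pixels of a logical matrix (0-based half-open coords)
box_from_mask <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask has no bounding box", call. = FALSE)
  bounding_box(min(idx[, 2L]) - 1L, min(idx[, 1L]) - 1L,
               max(idx[, 2L]), max(idx[, 1L]))
}
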