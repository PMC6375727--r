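#' Image field
#'
#' A 2-D intensity grid with a channel label and pixel size. Images are
#' stored as numeric matrices in row-major image convention: row index is
#' the y coordinate, column index the x coordinate, origin at the top-left,
#' y increasing downward. Integer pixel indices address pixel centers.
#'
#' @param pixels numeric matrix of finite, non-negative intensities.
#' @param channel `"fluorescence"` or `"brightfield"`.
#' @param pixel_size physical pixel size in micrometers per pixel.
#' @return an object of class `image_field`.
#' @export
image_field <- function(pixels,
                        channel = c("fluorescence", "brightfield"),
                        pixel_size = 1) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("pixels must be a numeric matrix")
  }
  if (any(!is.finite(pixels))) stop("pixel values must all be finite")
  if (any(pixels < 0)) stop("pixel values must all be >= 0")
  structure(
    list(pixels = pixels, channel = channel, pixel_size = pixel_size),
    class = "image_field"
  )
}

#' @export
print.image_field <- function(x, ...) {
  cat(sprintf(
    "<image_field> %d x %d px, channel = %s, pixel_size = %g um/px\n",
    nrow(x$pixels), ncol(x$pixels), x$channel, x$pixel_size
  ))
  invisible(x)
}

#' @export
dim.image_field <- function(x) dim(x$pixels)

#' ROI polygon
#'
#' A simple closed polygon delimiting a region of interest (growth cone,
#' background region, tract, ...). Vertices are in pixel coordinates
#' (x right, y down); the polygon is implicitly closed.
#'
#' @param x,y numeric vertex coordinates (equal length, >= 3).
#' @param label text label for the region.
#' @return an object of class `roi_polygon`.
#' @export
roi_polygon <- function(x, y, label = "roi") {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("a polygon needs at least 3 vertices")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("polygon vertices must be finite")
  }
  structure(
    list(x = as.numeric(x), y = as.numeric(y), label = as.character(label)),
    class = "roi_polygon"
  )
}

#' @export
print.roi_polygon <- function(x, ...) {
  cat(sprintf(
    "<roi_polygon> '%s', %d vertices, bbox x [%.1f, %.1f] y [%.1f, %.1f]\n",
    x$label, length(x$x), min(x$x), max(x$x), min(x$y), max(x$y)
  ))
  invisible(x)
}

#' Bisection line through a growth cone
#'
#' The line that divides a growth cone into the near (cue-facing) and far
#' halves. It passes through `anchor` along `direction` (the axon-shaft
#' axis). The side of a pixel p is `sign(cross(direction, p - anchor))`;
#' `near_side_sign` states which sign faces the cue source. Pixels exactly
#' on the line are assigned to the near side.
#'
#' @param anchor length-2 point on the line (x, y).
#' @param direction length-2 vector along the line; normalized internally.
#' @param near_side_sign +1 or -1.
#' @return an object of class `bisection_line`.
#' @export
bisection_line <- function(anchor, direction, near_side_sign) {
  if (length(anchor) != 2 || length(direction) != 2) {
    stop("anchor and direction must have length 2")
  }
  if (!near_side_sign %in% c(-1, 1)) stop("near_side_sign must be +1 or -1")
  structure(
    list(
      anchor = as.numeric(anchor),
      direction = normalize(as.numeric(direction)),
      near_side_sign = as.integer(near_side_sign)
    ),
    class = "bisection_line"
  )
}

# Coordinates of all pixel centers of an image, as an n x 2 matrix (x, y).
pixel_centers <- function(img) {
  d <- dim(img$pixels)
  cbind(
    x = rep(seq_len(d[2]), each = d[1]),
    y = rep(seq_len(d[1]), times = d[2])
  )
}

#' Pixel mask of an ROI polygon
#'
#' Logical matrix (same shape as the image) marking pixels whose centers
#' lie inside the polygon.
#'
#' @param img an [image_field].
#' @param roi an [roi_polygon].
#' @return logical matrix.
#' @export
roi_pixel_mask <- function(img, roi) {
  stopifnot(inherits(img, "image_field"), inherits(roi, "roi_polygon"))
  pts <- pixel_centers(img)
  bnd <- cbind(c(roi$x, roi$x[1]), c(roi$y, roi$y[1]))
  inside <- mgcv::in.out(bnd, cbind(pts[, 1], pts[, 2]))
  matrix(inside, nrow = nrow(img$pixels), ncol = ncol(img$pixels))
}
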