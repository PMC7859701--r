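#' Polyline trace in pixel coordinates
#'
#' An ordered, open polyline in 0-based pixel coordinates. The first anchor
#' is the proximal (ciliary base) end by convention; every profile extracted
#' along a polyline therefore runs proximal to distal.
#'
#' @param x,y numeric vectors of anchor coordinates (0-based pixels).
#' @return An object of class `polyline`.
#' @export
polyline <- function(x, y) {
  check_that(is.numeric(x) && is.numeric(y) && length(x) == length(y),
             "x and y must be numeric vectors of equal length")
  check_that(length(x) >= 2, "a polyline needs at least 2 anchor points")
  check_that(all(is.finite(x)) && all(is.finite(y)),
             "anchor coordinates must be finite")
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  check_that(sum(seg) > 0, "polyline must have positive arc length")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 seg_lengths = seg, cum_length = c(0, cumsum(seg))),
            class = "polyline")
}

#' @export
print.polyline <- function(x, ...) {
  cat(sprintf("<polyline> %d anchors, arc length %.3f px\n",
              length(x$x), sum(x$seg_lengths)))
  invisible(x)
}

#' Physical length of a polyline trace
#'
#' Sum of Euclidean segment lengths times the pixel size: the path length
#' of a segmented-line trace (cilium or dendrite), not the end-to-end chord.
#'
#' @param line a [polyline].
#' @param pixel_size_um pixel size in micrometres.
#' @return Length in micrometres.
#' @export
trace_length <- function(line, pixel_size_um) {
  check_that(inherits(line, "polyline"), "line must be a polyline")
  check_that(pixel_size_um > 0, "pixel_size_um must be positive")
  sum(line$seg_lengths) * pixel_size_um
}

# point and unit tangent at arc position s (pixels) along the polyline
polyline_point <- function(line, s) {
  cl <- line$cum_length
  n <- length(cl)
  s <- pmin(pmax(s, 0), cl[n])
  i <- findInterval(s, cl, rightmost.closed = TRUE)
  i <- pmin(i, n - 1L)
  f <- (s - cl[i]) / line$seg_lengths[i]
  dx <- (line$x[i + 1] - line$x[i]) / line$seg_lengths[i]
  dy <- (line$y[i + 1] - line$y[i]) / line$seg_lengths[i]
  list(x = line$x[i] + f * line$seg_lengths[i] * dx,
       y = line$y[i] + f * line$seg_lengths[i] * dy,
       tx = dx, ty = dy)
}

#' Point set with an anatomical axis
#'
#' A set of 2D points (e.g. amphid basal-body positions from a maximum
#' projection) together with the anterior-posterior axis direction along
#' which spans are measured.
#'
#' @param x,y numeric point coordinates (0-based pixels).
#' @param axis length-2 numeric axis direction (need not be normalised).
#' @return An object of class `point_set`.
#' @export
point_set <- function(x, y, axis = c(1, 0)) {
  check_that(is.numeric(x) && is.numeric(y) && length(x) == length(y),
             "x and y must be numeric vectors of equal length")
  check_that(length(x) >= 1, "point set needs at least one point")
  check_that(length(axis) == 2 && sum(axis^2) > 0,
             "axis must be a nonzero length-2 vector")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 axis = axis / sqrt(sum(axis^2))),
            class = "point_set")
}

#' Span of a point set along its anatomical axis
#'
#' Side length, along the anatomical axis, of the minimal bounding box of
#' the points (the box a user would draw around the basal bodies after
#' rotating the axis onto the grid). A single point has span 0.
#'
#' @param points a [point_set].
#' @param pixel_size_um pixel size in micrometres.
#' @return Span in micrometres.
#' @export
bb_span <- function(points, pixel_size_um) {
  check_that(inherits(points, "point_set"), "points must be a point_set")
  check_that(pixel_size_um > 0, "pixel_size_um must be positive")
  proj <- points$x * points$axis[1] + points$y * points$axis[2]
  (max(proj) - min(proj)) * pixel_size_um
}
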