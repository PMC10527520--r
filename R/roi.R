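#' Rectangular region of interest
#'
#' An ROI is an axis-aligned rectangle in sample coordinates (nanometres).
#' Point membership uses the half-open convention `[min, max)` on both axes,
#' so adjacent ROIs tile a field without double-counting boundary points.
#'
#' @param x_min,x_max,y_min,y_max Rectangle bounds in nm; `x_min < x_max`,
#'   `y_min < y_max`.
#' @return An object of class `roi`.
#' @examples
#' r <- roi(0, 2000, 0, 2000)
#' roi_area(r) # 4e6 nm^2 = 4 um^2
#' @export
roi <- function(x_min, x_max, y_min, y_max) {
  vals <- c(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max)
  if (any(!is.finite(vals)))
    stop("ROI bounds must be finite")
  if (x_min >= x_max || y_min >= y_max)
    stop("ROI must satisfy x_min < x_max and y_min < y_max")
  structure(as.list(vals), class = "roi")
}

#' @rdname roi
#' @param r An `roi` object.
#' @export
roi_area <- function(r) {
  stopifnot(inherits(r, "roi"))
  (r$x_max - r$x_min) * (r$y_max - r$y_min)
}

#' @rdname roi
#' @export
roi_sides <- function(r) {
  stopifnot(inherits(r, "roi"))
  c(width = r$x_max - r$x_min, height = r$y_max - r$y_min)
}

#' @rdname roi
#' @param x,y Numeric vectors of coordinates in nm.
#' @export
roi_contains <- function(r, x, y) {
  stopifnot(inherits(r, "roi"))
  x >= r$x_min & x < r$x_max & y >= r$y_min & y < r$y_max
}

# shrink the rectangle by `margin` nm on every side (border-exclusion
# edge correction); may be empty, caller must check
roi_erode <- function(r, margin) {
  if (r$x_min + margin >= r$x_max - margin ||
      r$y_min + margin >= r$y_max - margin)
    return(NULL)
  roi(r$x_min + margin, r$x_max - margin,
      r$y_min + margin, r$y_max - margin)
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("ROI [%g, %g) x [%g, %g) nm (%.3g um^2)\n",
              x$x_min, x$x_max, x$y_min, x$y_max, roi_area(x) / 1e6))
  invisible(x)
}

#' @export
format.roi <- function(x, ...) {
  sprintf("[%g,%g)x[%g,%g)", x$x_min, x$x_max, x$y_min, x$y_max)
}
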