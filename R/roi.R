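#' Region of interest (ROI) polygon
#'
#' An ROI is a simple (non-self-intersecting) closed polygon in pixel
#' coordinates delineating the analysed tissue area, typically drawn around
#' predominantly tumor-epithelial regions. Cell densities are reported per
#' mm^2 using the physical pixel spacing.
#'
#' @param x,y Numeric vertex coordinates of the polygon ring (the first
#'   vertex is not repeated at the end). Pixel units, x = column, y = row,
#'   0-based, origin at the top-left.
#' @param pixel_spacing_um Physical size of one pixel side in micrometres
#'   (default 0.33, the sampling spacing of a 20x hyperspectral scan).
#' @return An object of class `roi` with fields `x`, `y`,
#'   `pixel_spacing_um`, `area_px2` and `area_mm2`.
#' @examples
#' r <- roi(c(0, 100, 100, 0), c(0, 0, 100, 100))
#' r$area_mm2
#' @export
roi <- function(x, y, pixel_spacing_um = 0.33) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n < 3 || length(y) != n) {
    stop("an ROI polygon needs at least 3 vertices with matching x and y")
  }
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    stop("ROI vertices must be finite")
  }
  if (pixel_spacing_um <= 0) stop("pixel_spacing_um must be > 0")
  # simplicity: no two non-adjacent edges may properly cross
  for (i in seq_len(n)) {
    i2 <- i %% n + 1
    for (j in seq_len(n)) {
      if (j <= i) next
      j2 <- j %% n + 1
      if (j == i2 || j2 == i) next # adjacent edges share a vertex
      if (segments_cross(x[i], y[i], x[i2], y[i2], x[j], y[j], x[j2], y[j2])) {
        stop("ROI polygon is self-intersecting (edges ", i, " and ", j, ")")
      }
    }
  }
  area <- polygon_area(x, y)
  if (area <= 0) stop("ROI polygon has zero area")
  structure(
    list(x = x, y = y, pixel_spacing_um = pixel_spacing_um,
         area_px2 = area,
         area_mm2 = area * (pixel_spacing_um / 1000)^2),
    class = "roi"
  )
}

#' Rectangular ROI helper
#'
#' @param xmin,ymin,xmax,ymax Rectangle corners in pixel coordinates.
#' @inheritParams roi
#' @return An `roi` object.
#' @export
rect_roi <- function(xmin, ymin, xmax, ymax, pixel_spacing_um = 0.33) {
  stopifnot(xmax > xmin, ymax > ymin)
  roi(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax),
      pixel_spacing_um = pixel_spacing_um)
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("ROI polygon: %d vertices, %.0f px^2 (%.4f mm^2 at %.2f um/px)\n",
              length(x$x), x$area_px2, x$area_mm2, x$pixel_spacing_um))
  invisible(x)
}

roi_bbox <- function(roi) {
  c(xmin = min(roi$x), ymin = min(roi$y), xmax = max(roi$x), ymax = max(roi$y))
}

#' Test whether points lie inside an ROI
#' @param roi An `roi` object.
#' @param x,y Point coordinates.
#' @return Logical vector.
#' @export
roi_contains <- function(roi, x, y) {
  point_in_polygon(x, y, roi$x, roi$y)
}
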