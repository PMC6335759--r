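# Small planar-geometry utilities used by the ROI and neighbor-graph code.
# Coordinates are pixel units, x = column, y = row, 0-based, origin top-left.

#' Signed and absolute polygon area (shoelace formula)
#' @param x,y numeric vertex coordinates of a closed ring (first vertex not
#'   repeated).
#' @return Absolute enclosed area in squared input units.
#' @keywords internal
polygon_area <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3, length(y) == n)
  x2 <- c(x[-1], x[1])
  y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

#' Vectorized ray-casting point-in-polygon test
#'
#' Points exactly on the boundary may fall on either side; callers that care
#' shrink or expand the polygon by an epsilon.
#'
#' @param px,py numeric point coordinates.
#' @param poly_x,poly_y polygon ring vertices.
#' @return Logical vector.
#' @keywords internal
point_in_polygon <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly_x[i]; yi <- poly_y[i]
    xj <- poly_x[j]; yj <- poly_y[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Proper intersection test for two segments (shared endpoints do not count),
# used to validate that an ROI ring is simple.
segments_cross <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  o <- function(px, py, qx, qy, rx, ry) {
    sign((qx - px) * (ry - py) - (qy - py) * (rx - px))
  }
  o1 <- o(ax, ay, bx, by, cx, cy)
  o2 <- o(ax, ay, bx, by, dx, dy)
  o3 <- o(cx, cy, dx, dy, ax, ay)
  o4 <- o(cx, cy, dx, dy, bx, by)
  (o1 != o2) && (o3 != o4) && all(c(o1, o2, o3, o4) != 0)
}

#' Length of the part of a segment lying inside a simple polygon
#'
#' Splits the segment at every crossing with a polygon edge and keeps the
#' sub-intervals whose midpoints pass the point-in-polygon test.
#'
#' @param x1,y1,x2,y2 segment endpoints.
#' @param poly_x,poly_y polygon ring.
#' @return Non-negative length.
#' @keywords internal
segment_length_in_polygon <- function(x1, y1, x2, y2, poly_x, poly_y) {
  dx <- x2 - x1; dy <- y2 - y1
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) return(0)
  n <- length(poly_x)
  ex1 <- poly_x; ey1 <- poly_y
  ex2 <- c(poly_x[-1], poly_x[1]); ey2 <- c(poly_y[-1], poly_y[1])
  # solve p1 + t*d = e1 + s*(e2-e1) for each edge
  fx <- ex2 - ex1; fy <- ey2 - ey1
  denom <- dx * fy - dy * fx
  ts <- rep(NA_real_, n)
  ok <- abs(denom) > 1e-300
  t <- ((ex1 - x1) * fy - (ey1 - y1) * fx) / denom
  s <- ((ex1 - x1) * dy - (ey1 - y1) * dx) / denom
  keep <- ok & t >= 0 & t <= 1 & s >= 0 & s <= 1
  cuts <- sort(unique(c(0, 1, t[keep])))
  mids_t <- (cuts[-1] + cuts[-length(cuts)]) / 2
  mx <- x1 + mids_t * dx
  my <- y1 + mids_t * dy
  inside <- point_in_polygon(mx, my, poly_x, poly_y)
  sum((cuts[-1] - cuts[-length(cuts)])[inside]) * len
}

# TRUE when the ring is exactly an axis-aligned rectangle (so clipping the
# Voronoi diagram to the bounding box already clips it to the ROI).
ring_is_bbox <- function(x, y) {
  if (length(x) != 4) return(FALSE)
  xs <- sort(unique(x)); ys <- sort(unique(y))
  length(xs) == 2 && length(ys) == 2 &&
    all(table(paste(x, y)) == 1)
}
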