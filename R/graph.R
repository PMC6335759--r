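#' Build the Voronoi-adjacency neighbor graph of cells within an ROI
#'
#' Computes the Voronoi tessellation of the cell centroids, clips it to the
#' ROI polygon, and connects two cells whenever their clipped Voronoi
#' polygons share a boundary segment of positive length. The Voronoi polygon
#' approximates the cell boundary, so adjacent polygons correspond to cells
#' in physical contact; no distance cutoff is involved, which lets closely
#' packed immune cells and widely spaced tumor cells both be neighbors of
#' their actual contacts.
#'
#' Cells whose centroids fall outside the ROI are dropped (with a message
#' suppressed; the count is kept in the result). Duplicate centroids are
#' jittered by 1e-6 px with a warning. Point-contact corners arising from
#' cocircular degeneracies (for example four cells on a square) are not
#' neighbors: a shared boundary must be longer than `eps`.
#'
#' @param cells A data.frame with columns `id`, `x`, `y` (pixel coordinates)
#'   and optionally `phenotype`.
#' @param roi An [roi()] object.
#' @param eps Minimum shared-boundary length (px) for adjacency; default
#'   1e-9 px, which only excludes degenerate point contacts.
#' @return An object of class `neighbor_graph`: a list with `ids`, `x`, `y`,
#'   `phenotype` (or NULL), `edges` (data.frame `a`, `b`, `length_px`, ids
#'   with a < b position-wise), `adj` (adjacency list of integer indices),
#'   `roi`, and `n_dropped_outside`.
#' @examples
#' cells <- data.frame(id = 1:3, x = c(10, 30, 20), y = c(10, 10, 30))
#' g <- build_graph(cells, rect_roi(0, 0, 40, 40))
#' g$edges
#' @export
build_graph <- function(cells, roi, eps = 1e-9) {
  stopifnot(is.data.frame(cells), all(c("id", "x", "y") %in% names(cells)))
  if (!inherits(roi, "roi")) stop("roi must be an `roi` object")
  inside <- roi_contains(roi, cells$x, cells$y)
  n_out <- sum(!inside)
  cells <- cells[inside, , drop = FALSE]
  n <- nrow(cells)
  if (n < 3) stop("degenerate geometry: need at least 3 cells inside the ROI")
  x <- as.numeric(cells$x)
  y <- as.numeric(cells$y)

  dup <- duplicated(cbind(x, y))
  if (any(dup)) {
    warning(sum(dup), " duplicate centroid(s) jittered by 1e-6 px")
    x[dup] <- x[dup] + 1e-6 * seq_len(sum(dup))
    y[dup] <- y[dup] + 1e-6 * seq_len(sum(dup))
  }

  # collinearity check: all points on one line cannot form a 2-D tessellation
  if (n >= 3) {
    cx <- x - x[1]; cy <- y - y[1]
    cross <- cx[2] * cy - cy[2] * cx
    if (all(abs(cross) < 1e-9)) {
      stop("degenerate geometry: all cell centroids are collinear")
    }
  }

  bb <- roi_bbox(roi)
  res <- voronoi_adjacency_cpp(
    x, y,
    c(bb["xmin"], bb["xmax"], bb["xmax"], bb["xmin"]),
    c(bb["ymin"], bb["ymin"], bb["ymax"], bb["ymax"]),
    eps
  )

  # one record per directed half-edge; keep i < j once, lengths agree up to
  # floating error so the i-side value is used
  ii <- res$i; jj <- res$j
  keep <- ii < jj
  a <- ii[keep]; b <- jj[keep]
  x1 <- res$x1[keep]; y1 <- res$y1[keep]
  x2 <- res$x2[keep]; y2 <- res$y2[keep]

  # clip shared segments to the ROI when it is not its own bounding box
  if (!ring_is_bbox(roi$x, roi$y)) {
    len <- vapply(seq_along(a), function(k) {
      segment_length_in_polygon(x1[k], y1[k], x2[k], y2[k], roi$x, roi$y)
    }, numeric(1))
  } else {
    len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  }
  keep2 <- len > eps
  a <- a[keep2]; b <- b[keep2]; len <- len[keep2]

  edges <- data.frame(a = cells$id[a], b = cells$id[b], length_px = len)
  adj <- vector("list", n)
  for (k in seq_along(a)) {
    adj[[a[k]]] <- c(adj[[a[k]]], b[k])
    adj[[b[k]]] <- c(adj[[b[k]]], a[k])
  }

  structure(
    list(ids = cells$id, x = x, y = y,
         phenotype = if ("phenotype" %in% names(cells))
           as.character(cells$phenotype) else NULL,
         edges = edges, adj = adj, roi = roi,
         n_dropped_outside = n_out),
    class = "neighbor_graph"
  )
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("Voronoi neighbor graph: %d cells, %d edges (%d dropped outside ROI)\n",
              length(x$ids), nrow(x$edges), x$n_dropped_outside))
  invisible(x)
}

#' Neighbor cell ids of one cell
#' @param graph A `neighbor_graph`.
#' @param id A cell id present in the graph.
#' @return Integer vector of neighboring cell ids.
#' @export
graph_neighbors <- function(graph, id) {
  idx <- match(id, graph$ids)
  if (is.na(idx)) stop("cell id ", id, " is not in the graph")
  graph$ids[graph$adj[[idx]]]
}

# Directed index-pair edge list (both directions), the workhorse layout for
# frequency computations and label permutations.
directed_edges <- function(graph) {
  ai <- match(graph$edges$a, graph$ids)
  bi <- match(graph$edges$b, graph$ids)
  list(ei = c(ai, bi), ej = c(bi, ai), n = length(graph$ids))
}

#' Plot a neighbor graph
#'
#' Draws cell centroids colored by phenotype with neighbor links.
#'
#' @param x A `neighbor_graph`.
#' @param cells Optional cell table with `id` and `phenotype` to color by.
#' @param ... Passed to [graphics::points()].
#' @export
plot.neighbor_graph <- function(x, cells = NULL, ...) {
  ai <- match(x$edges$a, x$ids)
  bi <- match(x$edges$b, x$ids)
  plot(x$x, x$y, type = "n", xlab = "x (px)", ylab = "y (px)",
       ylim = rev(range(x$y)), asp = 1)
  segments(x$x[ai], x$y[ai], x$x[bi], x$y[bi], col = "grey80")
  ph <- x$phenotype
  if (!is.null(cells)) ph <- as.character(cells$phenotype)[match(x$ids, cells$id)]
  if (is.null(ph)) {
    points(x$x, x$y, pch = 19, ...)
  } else {
    lev <- sort(unique(ph))
    cols <- setNames(hcl.colors(max(3, length(lev)), "Dark 3")[seq_along(lev)], lev)
    points(x$x, x$y, pch = 19, col = cols[ph], ...)
    legend("topright", legend = lev, col = cols, pch = 19, cex = 0.8, bg = "white")
  }
  invisible(x)
}
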