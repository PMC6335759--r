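# Nuclei segmentation from the hematoxylin concentration map: iterative
# Otsu thresholding with size rules (remove < 50 px; re-threshold > 1000 px
# components at the higher Otsu level computed within the component;
# fragments >= 150 px become new objects, smaller ones rejoin their parent),
# with a distance-transform watershed after each iteration to split
# touching nuclei. Components are 8-connected throughout.

#' Otsu threshold of a numeric sample
#'
#' Maximizes the between-class variance over a 256-bin histogram spanning
#' the sample's min-max range; `values > threshold` is the foreground. For
#' well-separated modes every cut through the empty gap maximizes the
#' criterion, so ties are broken at the middle of the maximizing plateau.
#' Scale-invariant: `otsu_threshold(k * v) == k * otsu_threshold(v)` for
#' `k > 0`.
#'
#' @param values Numeric vector (finite).
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold, or `NA` if the sample is constant.
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  values <- values[is.finite(values)]
  lo <- min(values); hi <- max(values)
  if (length(values) == 0 || hi == lo) return(NA_real_)
  bin <- pmin(pmax(ceiling((values - lo) / (hi - lo) * n_bins), 1L), n_bins)
  h <- tabulate(bin, nbins = n_bins)
  w <- cumsum(h)
  mids <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  m <- cumsum(h * mids)
  n <- w[n_bins]; mt <- m[n_bins]
  w0 <- w[-n_bins]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- m[-n_bins] / w0
  mu1 <- (mt - m[-n_bins]) / w1
  bcv <- w0 * w1 * (mu0 - mu1)^2
  bcv[!valid] <- -Inf
  k <- mean(which(bcv == max(bcv))) # middle of the maximizing plateau
  lo + k * (hi - lo) / n_bins
}

# 8-connected labelling (C++ union-find) returning an integer matrix
label_components <- function(mask) {
  label8_cpp(mask)
}

component_sizes <- function(lab) {
  if (max(lab) == 0) return(integer(0))
  tabulate(lab[lab > 0], nbins = max(lab))
}

# drop components smaller than min_size and relabel 1..K contiguously
filter_small <- function(lab, min_size) {
  sz <- component_sizes(lab)
  if (length(sz) == 0) return(lab)
  keep <- which(sz >= min_size)
  remap <- integer(length(sz))
  remap[keep] <- seq_along(keep)
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

# Watershed split of a single object mask on its Euclidean distance
# transform; regional maxima closer than `h` in distance units are merged
# (EBImage's `tolerance`), which suppresses spurious splits from boundary
# roughness. Regions below min_size are absorbed into the largest region.
watershed_split <- function(mask, h, min_size) {
  dm <- EBImage::distmap(mask)
  ws <- EBImage::watershed(dm, tolerance = h, ext = 1)
  ws <- as.matrix(EBImage::imageData(ws))
  nr <- max(ws)
  if (nr <= 1) return(mask)
  sz <- tabulate(ws[ws > 0], nbins = nr)
  big <- which(sz >= min_size)
  if (length(big) <= 1) return(mask)
  main <- which.max(sz)
  remap <- integer(nr)
  remap[big] <- seq_along(big)
  remap[remap == 0] <- remap[main]
  out <- ws
  out[ws > 0] <- remap[ws[ws > 0]]
  out
}

#' Segment nuclei from a hematoxylin concentration map
#'
#' Iterative Otsu segmentation: (1) global Otsu threshold; components below
#' `min_size` px are removed; (2) each component above `split_size` px is
#' re-thresholded at the (necessarily higher) Otsu level computed from its
#' own pixels; resulting fragments of at least `fragment_size` px become new
#' objects while smaller fragments stay with the parent; (3) after every
#' iteration each object is examined with a Euclidean distance transform and
#' watershed (h-maxima tolerance `h_px`) and split where the watershed finds
#' multiple basins; (4) objects still above `split_size` px are reprocessed
#' for up to `max_iter` iterations in total. Components are 8-connected.
#'
#' @param map 2-D non-negative numeric matrix (hematoxylin concentration).
#' @param min_size Minimum object size in px (default 50).
#' @param split_size Size above which objects are re-thresholded (default
#'   1000).
#' @param fragment_size Minimum fragment size to become a new object
#'   (default 150).
#' @param max_iter Maximum re-threshold iterations (default 3).
#' @param h_px Watershed h-maxima tolerance in px (default 2).
#' @param pixel_spacing_um Physical pixel size recorded on the result.
#' @return Object of class `label_image`: list with `labels` (integer
#'   matrix, 0 background, 1..K nuclei) and `pixel_spacing_um`.
#' @export
segment_nuclei <- function(map, min_size = 50, split_size = 1000,
                           fragment_size = 150, max_iter = 3, h_px = 2,
                           pixel_spacing_um = 0.33) {
  stopifnot(is.matrix(map))
  if (!all(is.finite(map))) stop("input error: map contains non-finite values")
  empty <- structure(list(labels = matrix(0L, nrow(map), ncol(map)),
                          pixel_spacing_um = pixel_spacing_um),
                     class = "label_image")
  if (all(map == 0)) return(empty)

  t0 <- otsu_threshold(map)
  if (is.na(t0)) return(empty)
  lab <- label_components(map > t0)
  lab <- filter_small(lab, min_size)
  if (max(lab) == 0) return(empty)

  for (iter in seq_len(max_iter)) {
    sz <- component_sizes(lab)
    big <- which(sz > split_size)
    if (iter > 1 && length(big) == 0) break

    # re-threshold oversized components at their internal Otsu level
    for (l in big) {
      px <- lab == l
      t1 <- otsu_threshold(map[px])
      if (is.na(t1)) next
      sub <- px & map > t1
      frag <- label_components(sub)
      fsz <- component_sizes(frag)
      new_frags <- which(fsz >= fragment_size)
      if (length(new_frags) <= 1) next # nothing split off; keep parent whole
      # the largest fragment keeps the parent's label; the rest become new
      # objects; sub-threshold pixels and small fragments remain the parent's
      keep_as_parent <- new_frags[which.max(fsz[new_frags])]
      nxt <- max(lab)
      for (f in setdiff(new_frags, keep_as_parent)) {
        nxt <- nxt + 1L
        lab[frag == f] <- nxt
      }
    }

    # watershed pass over every object
    sz <- component_sizes(lab)
    nxt <- length(sz)
    for (l in which(sz >= min_size)) {
      px <- lab == l
      ws <- watershed_split(px, h_px, min_size)
      k <- max(ws)
      if (k > 1) {
        for (r in 2:k) {
          nxt <- nxt + 1L
          lab[ws == r] <- nxt
        }
      }
    }

    sz <- component_sizes(lab)
    if (!any(sz > split_size)) break
  }

  lab <- filter_small(lab, min_size)
  structure(list(labels = lab, pixel_spacing_um = pixel_spacing_um),
            class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  cat(sprintf("Label image: %d x %d px, %d nuclei (%.2f um/px)\n",
              nrow(x$labels), ncol(x$labels), max(x$labels),
              x$pixel_spacing_um))
  invisible(x)
}

#' Refine nucleus boundaries by trimming dim rim pixels
#'
#' A simple boundary refinement: every boundary pixel of a nucleus (a pixel
#' with an 8-neighbor outside the nucleus) whose map intensity is below
#' `cutoff` times the nucleus's own Otsu level is reassigned to background.
#' Removals that would empty a nucleus or break it into several pieces are
#' reverted, so the label count and one-component-per-label topology are
#' preserved.
#'
#' @param labimg A [segment_nuclei()] result.
#' @param map The concentration map the labels came from.
#' @param cutoff Fraction of the per-nucleus Otsu level below which boundary
#'   pixels are trimmed (default 0.5).
#' @return A `label_image` with the same labels, possibly smaller areas.
#' @export
refine_boundaries <- function(labimg, map, cutoff = 0.5) {
  stopifnot(inherits(labimg, "label_image"), is.matrix(map))
  lab <- labimg$labels
  stopifnot(all(dim(lab) == dim(map)))
  K <- max(lab)
  if (K == 0) return(labimg)
  nr <- nrow(lab); nc <- ncol(lab)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- lab
  # boundary: any of the 8 shifted copies differs from the center label
  is_boundary <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    shifted <- pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    is_boundary <- is_boundary | (shifted != lab)
  }
  is_boundary <- is_boundary & lab > 0

  out <- lab
  for (l in seq_len(K)) {
    px <- lab == l
    level <- otsu_threshold(map[px])
    if (is.na(level)) next
    drop <- px & is_boundary & map < cutoff * level
    if (!any(drop)) next
    trial <- px & !drop
    if (!any(trial)) next # would erase the nucleus entirely
    comp <- label_components(trial)
    if (max(comp) > 1) next # would disconnect it
    out[drop] <- 0L
  }
  structure(list(labels = out, pixel_spacing_um = labimg$pixel_spacing_um),
            class = "label_image")
}

#' Per-nucleus centroid and area table
#'
#' @param labimg A `label_image`.
#' @return data.frame with `id`, `x`, `y` (0-based pixel coordinates,
#'   x = column), `area_px`.
#' @export
label_table <- function(labimg) {
  lab <- labimg$labels
  K <- max(lab)
  if (K == 0) {
    return(data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      area_px = integer(0)))
  }
  idx <- which(lab > 0)
  l <- lab[idx]
  r <- (idx - 1) %% nrow(lab) + 1
  cc <- (idx - 1) %/% nrow(lab) + 1
  data.frame(
    id = seq_len(K),
    x = as.numeric(tapply(cc - 1, l, mean)),
    y = as.numeric(tapply(r - 1, l, mean)),
    area_px = as.integer(tabulate(l, nbins = K))
  )
}
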