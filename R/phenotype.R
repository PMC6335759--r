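# Cell phenotyping from per-stain integrated intensities: per-slide
# positivity thresholds feed a three-level binary decision tree over
# CD3/CD8/CD79a (8 leaves), followed by resolution of incompatible-marker
# conflicts (overlapping T and B cells are split in two; non-overlapping
# double positives are excluded; CD3-CD8+ cells are returned to the
# unstained group to preserve the tissue architecture).

MARKER_STAINS <- c("cd3", "cd8", "cd79a")

#' Integrate stain intensities over segmented nuclei
#'
#' For each nucleus and stain, sums the concentration map over the nucleus
#' mask; for membrane markers (by default every stain except hematoxylin) a
#' disc dilation of `ring_px` is applied to the nucleus mask first, so that
#' membrane staining just outside the nuclear boundary is captured. The
#' dilated mask may overlap neighboring nuclei; the integration is
#' deterministic and symmetric in that case. Intensity-weighted stain
#' centroids within the dilated mask are also reported (columns
#' `cx_<stain>`, `cy_<stain>`); they drive the overlap heuristic of
#' [resolve_conflicts()].
#'
#' @param labimg A [segment_nuclei()] result.
#' @param maps A [mcr_als_unmix()] result, or a named list of 2-D arrays
#'   aligned with the label image.
#' @param ring_px Dilation radius in px for membrane stains (default 2; 0
#'   integrates over the nucleus only).
#' @param ring_stains Stains integrated over the dilated mask (default all
#'   but `hematoxylin`).
#' @return data.frame: `id`, `x`, `y`, `area_px`, one `I_<stain>` column per
#'   stain, and `cx_<stain>`/`cy_<stain>` weighted centroids (NA when the
#'   stain has zero mass on the cell).
#' @export
integrate_intensity <- function(labimg, maps, ring_px = 2,
                                ring_stains = NULL) {
  stopifnot(inherits(labimg, "label_image"))
  if (inherits(maps, "concentration_maps")) maps <- maps$maps
  stopifnot(is.list(maps), !is.null(names(maps)))
  lab <- labimg$labels
  for (m in maps) {
    if (!all(dim(m) == dim(lab))) stop("input error: map/label shape mismatch")
  }
  if (is.null(ring_stains)) ring_stains <- setdiff(names(maps), "hematoxylin")
  cells <- label_table(labimg)
  K <- nrow(cells)
  for (s in names(maps)) {
    cells[[paste0("I_", s)]] <- numeric(K)
    cells[[paste0("cx_", s)]] <- NA_real_
    cells[[paste0("cy_", s)]] <- NA_real_
  }
  if (K == 0) return(cells)

  brush <- if (ring_px > 0) {
    EBImage::makeBrush(2 * ring_px + 1, shape = "disc")
  } else NULL
  nr <- nrow(lab); nc <- ncol(lab)

  for (k in seq_len(K)) {
    px <- which(lab == cells$id[k])
    r <- (px - 1) %% nr + 1
    cc <- (px - 1) %/% nr + 1
    # bounding window with a margin for the dilation
    r0 <- max(1, min(r) - ring_px); r1 <- min(nr, max(r) + ring_px)
    c0 <- max(1, min(cc) - ring_px); c1 <- min(nc, max(cc) + ring_px)
    m0 <- matrix(0, r1 - r0 + 1, c1 - c0 + 1)
    m0[cbind(r - r0 + 1, cc - c0 + 1)] <- 1
    md <- if (!is.null(brush)) {
      as.matrix(EBImage::imageData(EBImage::dilate(m0, brush))) > 0
    } else m0 > 0
    win_r <- r0:r1; win_c <- c0:c1
    for (s in names(maps)) {
      sub <- maps[[s]][win_r, win_c, drop = FALSE]
      use <- if (s %in% ring_stains) md else m0 > 0
      w <- sub * use
      tot <- sum(w)
      cells[[paste0("I_", s)]][k] <- tot
      if (tot > 0) {
        wc <- colSums(w); wr <- rowSums(w)
        cells[[paste0("cx_", s)]][k] <- sum(wc * (win_c - 1)) / tot
        cells[[paste0("cy_", s)]][k] <- sum(wr * (win_r - 1)) / tot
      }
    }
  }
  cells
}

#' Per-stain positivity thresholds
#'
#' One threshold per stain per slide, applied to every area imaged from that
#' slide. `scale_direction = "above"` (the default) calls a cell positive
#' when its integrated intensity exceeds the threshold, the natural
#' direction for concentration-scale data. Legacy threshold sets drawn on
#' inverted 0-255 intensity scales (where positive cells fall *below* the
#' threshold) can be imported with `scale_direction = "below"`.
#'
#' @param thresholds Named numeric vector; names must include the marker
#'   stains (`cd3`, `cd8`, `cd79a`).
#' @param scale_direction `"above"` or `"below"`.
#' @return Object of class `threshold_set`.
#' @export
threshold_set <- function(thresholds, scale_direction = c("above", "below")) {
  scale_direction <- match.arg(scale_direction)
  stopifnot(is.numeric(thresholds), !is.null(names(thresholds)))
  missing <- setdiff(MARKER_STAINS, names(thresholds))
  if (length(missing) > 0) {
    stop("missing threshold(s) for: ", paste(missing, collapse = ", "))
  }
  structure(list(thresholds = thresholds, scale_direction = scale_direction),
            class = "threshold_set")
}

#' Automatic per-stain thresholds from the integrated-intensity histogram
#'
#' Applies [otsu_threshold()] to each marker's integrated intensities across
#' all cells of a slide; a hands-off default standing in for interactive
#' visual threshold selection.
#'
#' @param cells Cell table from [integrate_intensity()] (pooled over the
#'   slide's areas).
#' @param stains Stains to threshold (default the marker stains).
#' @return A [threshold_set()].
#' @export
auto_thresholds <- function(cells, stains = MARKER_STAINS) {
  th <- vapply(stains, function(s) {
    v <- cells[[paste0("I_", s)]]
    if (is.null(v)) stop("input error: missing column I_", s)
    t <- otsu_threshold(v)
    if (is.na(t)) max(v) else t
  }, numeric(1))
  threshold_set(th, "above")
}

#' Classify cells into the 8 decision-tree groups
#'
#' Three binary positivity calls (CD3, CD8, CD79a) define `2^3 = 8` leaves,
#' recorded in `raw_group` as e.g. `"CD3+CD8-CD79a-"`. The leaf-to-phenotype
#' map is: CD3+CD8- -> `CD3_T`; CD3+CD8+ -> `CD3_CD8_T` (both with CD79a-);
#' CD3-CD8-CD79a+ -> `CD79A_B`; all-negative -> `UNSTAINED`; the rare
#' CD3-CD8+ leaves (with or without CD79a) -> `UNSTAINED` (kept to preserve
#' the tissue architecture); the two CD3+...CD79a+ leaves are marker
#' conflicts (T-lineage and B-lineage markers on one nucleus) and get
#' phenotype `CONFLICT` pending [resolve_conflicts()].
#'
#' @param cells Cell table with `I_cd3`, `I_cd8`, `I_cd79a` columns.
#' @param thresholds A [threshold_set()].
#' @return The cell table with logical `pos_cd3`, `pos_cd8`, `pos_cd79a`,
#'   `raw_group` and preliminary `phenotype` columns added.
#' @export
classify_cells <- function(cells, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  for (s in MARKER_STAINS) {
    col <- paste0("I_", s)
    if (is.null(cells[[col]])) stop("input error: missing column ", col)
    t <- thresholds$thresholds[[s]]
    cells[[paste0("pos_", s)]] <- if (thresholds$scale_direction == "above") {
      cells[[col]] > t
    } else {
      cells[[col]] < t
    }
  }
  sgn <- function(p) ifelse(p, "+", "-")
  cells$raw_group <- paste0("CD3", sgn(cells$pos_cd3),
                            "CD8", sgn(cells$pos_cd8),
                            "CD79a", sgn(cells$pos_cd79a))
  cells$phenotype <- raw_group_phenotype(cells$raw_group)
  cells
}

#' Map of all 8 decision-tree leaves to preliminary phenotypes
#' @return Named character vector, one entry per leaf.
#' @export
decision_tree_leaves <- function() {
  c("CD3-CD8-CD79a-" = "UNSTAINED",
    "CD3-CD8-CD79a+" = "CD79A_B",
    "CD3-CD8+CD79a-" = "UNSTAINED",   # rare; kept as unstained
    "CD3-CD8+CD79a+" = "UNSTAINED",   # rare; kept as unstained
    "CD3+CD8-CD79a-" = "CD3_T",
    "CD3+CD8+CD79a-" = "CD3_CD8_T",
    "CD3+CD8-CD79a+" = "CONFLICT",    # T + B markers on one nucleus
    "CD3+CD8+CD79a+" = "CONFLICT")
}

raw_group_phenotype <- function(raw_group) {
  unname(decision_tree_leaves()[raw_group])
}

#' Resolve incompatible-marker conflicts
#'
#' Cells carrying both T-lineage (CD3) and B-lineage (CD79a) markers are
#' usually two overlapping cells that the segmentation could not separate.
#' The automated stand-in for visual review is geometric: a conflicted cell
#' is deemed overlapping when the intensity-weighted centroids of the CD3
#' and CD79a stains within the (dilated) nucleus mask are at least
#' `min_offset_px` apart. Overlapping conflicts are split in two: the
#' original cell keeps its position and becomes the T cell (`CD3_CD8_T`
#' when CD8+, else `CD3_T`), and a new cell with `origin = "split_added"`
#' and the parent's id in `parent_id` is added at the CD79a-weighted
#' centroid as a `CD79A_B` cell. Conflicts failing the offset test are
#' marked `EXCLUDED`.
#'
#' @param cells Output of [classify_cells()]; the stain-centroid columns
#'   from [integrate_intensity()] must be present for splits to be possible
#'   (conflicted cells without them are excluded).
#' @param min_offset_px Minimum CD3-CD79a centroid offset for the overlap
#'   call (default 2 px).
#' @return The cell table with final `phenotype`, `origin` and `parent_id`
#'   columns; split conflicts add one row each at the end.
#' @export
resolve_conflicts <- function(cells, min_offset_px = 2) {
  if (is.null(cells$origin)) cells$origin <- "segmented"
  if (is.null(cells$parent_id)) cells$parent_id <- NA_integer_
  conf <- which(cells$phenotype == "CONFLICT")
  if (length(conf) == 0) return(cells)
  have_centroids <- all(c("cx_cd3", "cy_cd3", "cx_cd79a", "cy_cd79a") %in%
                          names(cells))
  added <- list()
  next_id <- max(cells$id) # numeric ids assumed
  for (k in conf) {
    off <- if (have_centroids) {
      sqrt((cells$cx_cd3[k] - cells$cx_cd79a[k])^2 +
             (cells$cy_cd3[k] - cells$cy_cd79a[k])^2)
    } else NA_real_
    if (is.finite(off) && off >= min_offset_px) {
      cells$phenotype[k] <- if (isTRUE(cells$pos_cd8[k])) "CD3_CD8_T" else "CD3_T"
      next_id <- next_id + 1
      new_row <- cells[k, , drop = FALSE]
      new_row$id <- next_id
      new_row$x <- cells$cx_cd79a[k]
      new_row$y <- cells$cy_cd79a[k]
      new_row$phenotype <- "CD79A_B"
      new_row$origin <- "split_added"
      new_row$parent_id <- cells$id[k]
      added[[length(added) + 1]] <- new_row
    } else {
      cells$phenotype[k] <- EXCLUDED_LABEL
    }
  }
  if (length(added) > 0) {
    cells <- rbind(cells, do.call(rbind, added))
    rownames(cells) <- NULL
  }
  cells
}

#' Full phenotyping step: classify then resolve conflicts
#'
#' @inheritParams classify_cells
#' @inheritParams resolve_conflicts
#' @return Cell table with final phenotypes (possibly with added rows for
#'   split overlapping cells).
#' @export
phenotype_cells <- function(cells, thresholds, min_offset_px = 2) {
  resolve_conflicts(classify_cells(cells, thresholds),
                    min_offset_px = min_offset_px)
}
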