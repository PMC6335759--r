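# Neighbor-frequency quantification ("cell sociology") on a Voronoi
# adjacency graph. EXCLUDED cells shape the tessellation but are invisible
# to the statistics: they are removed from both numerator and denominator of
# every frequency and from densities.

# labels aligned to graph$ids, from the graph itself or a cell table
graph_labels <- function(graph, cells = NULL) {
  if (!is.null(cells)) {
    stopifnot(all(c("id", "phenotype") %in% names(cells)))
    lab <- as.character(cells$phenotype)[match(graph$ids, cells$id)]
    if (anyNA(lab)) stop("some graph cells are missing from the cell table")
    return(lab)
  }
  if (is.null(graph$phenotype)) {
    stop("no phenotypes: supply a cell table or build the graph from cells with a phenotype column")
  }
  graph$phenotype
}

# Per-cell eligible-neighbor degree and per-cell count of neighbors with a
# given label; both exclude EXCLUDED neighbors.
cell_counts <- function(de, labels, neighbor) {
  elig <- labels[de$ej] != EXCLUDED_LABEL
  deg <- tabulate(de$ei[elig], nbins = de$n)
  cnt <- tabulate(de$ei[elig & labels[de$ej] == neighbor], nbins = de$n)
  list(deg = deg, cnt = cnt)
}

# Mean per-cell neighbor frequency of `neighbor` over focal cells with label
# `focal` and at least one eligible neighbor. Returns NaN when no such focal
# cell exists. The fast path shared by summaries and the Monte Carlo null.
mean_pair_frequency <- function(de, labels, focal, neighbor) {
  cc <- cell_counts(de, labels, neighbor)
  f <- labels == focal & cc$deg > 0 & labels != EXCLUDED_LABEL
  mean(cc$cnt[f] / cc$deg[f])
}

#' Neighbor frequency of one phenotype around one focal cell
#'
#' The fraction of the focal cell's Voronoi neighbors that carry the given
#' phenotype, among neighbors that are not EXCLUDED. A cell with five
#' neighbors of which one is red has a red-neighbor frequency of 1/5 = 0.2.
#'
#' @param graph A [build_graph()] result.
#' @param cell_id Focal cell id.
#' @param neighbor Phenotype label counted in the numerator.
#' @param cells Optional cell table (`id`, `phenotype`) if the graph was
#'   built without phenotypes.
#' @return A fraction in `[0, 1]`, or `NaN` if the focal cell has no
#'   eligible neighbors.
#' @export
neighbor_frequency <- function(graph, cell_id, neighbor, cells = NULL) {
  labels <- graph_labels(graph, cells)
  idx <- match(cell_id, graph$ids)
  if (is.na(idx)) stop("cell id ", cell_id, " is not in the graph")
  nb <- graph$adj[[idx]]
  nb_lab <- labels[nb]
  nb_lab <- nb_lab[nb_lab != EXCLUDED_LABEL]
  if (length(nb_lab) == 0) return(NaN)
  sum(nb_lab == neighbor) / length(nb_lab)
}

#' Per-cell neighbor-frequency matrix
#'
#' @inheritParams neighbor_frequency
#' @param phenotypes Labels to report columns for; defaults to all
#'   non-EXCLUDED labels present.
#' @return A data.frame with `id`, `phenotype`, `n_neighbors` (eligible) and
#'   one `f_<label>` column per phenotype. Cells without eligible neighbors
#'   get NaN frequencies; EXCLUDED focal cells are omitted.
#' @export
cell_frequencies <- function(graph, cells = NULL, phenotypes = NULL) {
  labels <- graph_labels(graph, cells)
  de <- directed_edges(graph)
  if (is.null(phenotypes)) {
    phenotypes <- sort(setdiff(unique(labels), EXCLUDED_LABEL))
  }
  elig <- labels[de$ej] != EXCLUDED_LABEL
  deg <- tabulate(de$ei[elig], nbins = de$n)
  out <- data.frame(id = graph$ids, phenotype = labels, n_neighbors = deg)
  for (p in phenotypes) {
    cnt <- tabulate(de$ei[elig & labels[de$ej] == p], nbins = de$n)
    out[[paste0("f_", p)]] <- ifelse(deg > 0, cnt / deg, NaN)
  }
  out[out$phenotype != EXCLUDED_LABEL, , drop = FALSE]
}

#' Summarize cell sociology and densities over an ROI
#'
#' For every ordered (focal, neighbor) phenotype pair, the mean and standard
#' deviation of the per-cell neighbor frequency over all focal cells of that
#' type with at least one eligible neighbor; focal cells with no eligible
#' neighbor are skipped (not counted as zero). Also reports per-phenotype
#' densities in cells/mm^2 using the ROI area. Neighbor frequency and
#' density are deliberately decoupled: two rare phenotypes that cluster
#' together have low densities but near-1 mutual neighbor frequencies.
#'
#' @inheritParams neighbor_frequency
#' @param phenotypes Labels to tabulate; defaults to all non-EXCLUDED labels
#'   present.
#' @return An object of class `sociology_result`: list with `frequencies`
#'   (data.frame `focal`, `neighbor`, `mean_frequency`, `sd_frequency`,
#'   `n_focal`), `densities` (data.frame `phenotype`, `n_cells`,
#'   `density_mm2`) and `roi_area_mm2`.
#' @examples
#' cells <- data.frame(id = 1:4, x = c(5, 25, 5, 25), y = c(5, 5, 25, 26),
#'                     phenotype = c("A", "A", "B", "A"))
#' g <- build_graph(cells, rect_roi(0, 0, 30, 30))
#' summarize_sociology(g)
#' @export
summarize_sociology <- function(graph, cells = NULL, phenotypes = NULL) {
  labels <- graph_labels(graph, cells)
  de <- directed_edges(graph)
  if (is.null(phenotypes)) {
    phenotypes <- sort(setdiff(unique(labels), EXCLUDED_LABEL))
  }
  elig <- labels[de$ej] != EXCLUDED_LABEL
  deg <- tabulate(de$ei[elig], nbins = de$n)

  rows <- expand.grid(neighbor = phenotypes, focal = phenotypes,
                      stringsAsFactors = FALSE)[, 2:1]
  rows$mean_frequency <- NA_real_
  rows$sd_frequency <- NA_real_
  rows$n_focal <- 0L
  for (p in phenotypes) {
    cnt <- tabulate(de$ei[elig & labels[de$ej] == p], nbins = de$n)
    for (f in phenotypes) {
      sel <- labels == f & deg > 0
      k <- which(rows$focal == f & rows$neighbor == p)
      rows$n_focal[k] <- sum(sel)
      if (any(sel)) {
        fr <- cnt[sel] / deg[sel]
        rows$mean_frequency[k] <- mean(fr)
        rows$sd_frequency[k] <- if (sum(sel) > 1) sd(fr) else 0
      }
    }
  }

  n_by <- vapply(phenotypes, function(p) sum(labels == p), integer(1))
  dens <- data.frame(phenotype = phenotypes, n_cells = n_by,
                     density_mm2 = n_by / graph$roi$area_mm2,
                     row.names = NULL)

  structure(list(frequencies = rows, densities = dens,
                 roi_area_mm2 = graph$roi$area_mm2),
            class = "sociology_result")
}

#' @export
print.sociology_result <- function(x, ...) {
  cat(sprintf("Cell sociology over %.4f mm^2\n", x$roi_area_mm2))
  cat("Densities (cells/mm^2):\n")
  print(x$densities, row.names = FALSE, digits = 4)
  cat("Mean neighbor frequencies (focal -> neighbor):\n")
  print(x$frequencies, row.names = FALSE, digits = 3)
  invisible(x)
}
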