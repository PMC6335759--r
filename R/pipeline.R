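# Top-level pipeline driver: unmix -> segment -> phenotype -> sociology ->
# montecarlo for a single ROI, with stage skipping when later-stage inputs
# are supplied directly.

RUN_CONFIG_KEYS <- c(
  "out_dir", "cube", "spectra", "cells", "roi", "thresholds",
  "scale_direction", "seed", "n_iter", "run_montecarlo", "pixel_spacing_um",
  "min_size", "split_size", "fragment_size", "max_iter", "ring_px",
  "min_offset_px", "refine_spectra", "tol", "roi_id"
)

#' Validate a pipeline run configuration
#'
#' Checks key names against the schema and basic types; unknown keys are
#' rejected with their JSON-pointer path.
#'
#' @param config A named list (or path to a JSON file).
#' @return The validated config list, with defaults filled in.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), RUN_CONFIG_KEYS)
  if (length(unknown) > 0) {
    stop("config error at /", unknown[1], ": unknown key")
  }
  if (is.null(config$out_dir)) stop("config error at /out_dir: required")
  if (is.null(config$cells) && is.null(config$cube)) {
    stop("config error at /cells: either cells or cube must be given")
  }
  if (is.null(config$roi)) stop("config error at /roi: required")
  defaults <- list(seed = 1L, n_iter = 500L, run_montecarlo = FALSE,
                   pixel_spacing_um = 0.33, min_size = 50, split_size = 1000,
                   fragment_size = 150, max_iter = 3, ring_px = 2,
                   min_offset_px = 2, refine_spectra = FALSE, tol = 1e-8,
                   thresholds = "auto", roi_id = "roi1")
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  if (config$n_iter < 2) stop("config error at /n_iter: must be >= 2")
  config
}

#' Run the analysis pipeline on one ROI
#'
#' Executes, in order, spectral unmixing, nuclei segmentation, phenotyping,
#' sociology quantification and (optionally) the Monte Carlo permutation
#' analysis, writing each stage's artifacts under `out_dir` along with a
#' provenance sidecar. Stages whose inputs are supplied directly are
#' skipped: passing `cells` (a CSV path or data.frame with phenotypes)
#' starts at the sociology stage.
#'
#' Re-running with an identical config and seed reproduces identical CSVs.
#'
#' @param config Named list or JSON path; see [validate_run_config()] for
#'   the schema. Main keys: `out_dir`; `cube` (TIFF path) + `spectra` (JSON
#'   path) or `cells` (CSV path / data.frame); `roi` (GeoJSON path or
#'   [roi()] object); `thresholds` (`"auto"` or a named list);
#'   `run_montecarlo`, `n_iter`, `seed`.
#' @return Invisibly, a list with the stage results and artifact paths.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  inputs <- character(0)
  artifacts <- list()

  roi_obj <- config$roi
  if (is.character(roi_obj)) {
    inputs <- c(inputs, roi_obj)
    roi_obj <- read_roi_geojson(roi_obj,
                                pixel_spacing_um = config$pixel_spacing_um)
  }
  stopifnot(inherits(roi_obj, "roi"))

  cells <- config$cells
  if (is.character(cells)) {
    inputs <- c(inputs, cells)
    cells <- read_cells_csv(cells)
  }

  if (is.null(cells)) {
    # --- unmix ---------------------------------------------------------
    inputs <- c(inputs, config$cube, sidecar_path(config$cube))
    cube <- read_cube_tiff(config$cube)
    if (is.null(config$spectra)) stop("config error at /spectra: required with cube")
    inputs <- c(inputs, config$spectra)
    sp <- read_spectra_json(config$spectra)
    od <- to_optical_density(cube)
    cmaps <- mcr_als_unmix(od, sp$spectra, tol = config$tol,
                           refine_spectra = isTRUE(config$refine_spectra))
    artifacts$maps <- write_maps_tiff(cmaps, file.path(out, "maps"))

    # --- segment -------------------------------------------------------
    labimg <- segment_nuclei(cmaps$maps$hematoxylin,
                             min_size = config$min_size,
                             split_size = config$split_size,
                             fragment_size = config$fragment_size,
                             max_iter = config$max_iter,
                             pixel_spacing_um = config$pixel_spacing_um)
    labimg <- refine_boundaries(labimg, cmaps$maps$hematoxylin)
    artifacts$labels <- write_labels_tiff(labimg, file.path(out, "labels.tif"))

    # --- phenotype -----------------------------------------------------
    cells <- integrate_intensity(labimg, cmaps, ring_px = config$ring_px)
    th <- if (identical(config$thresholds, "auto")) {
      auto_thresholds(cells)
    } else {
      threshold_set(unlist(config$thresholds),
                    scale_direction = if (is.null(config$scale_direction))
                      "above" else config$scale_direction)
    }
    cells <- phenotype_cells(cells, th, min_offset_px = config$min_offset_px)
    artifacts$cells <- write_cells_csv(cells, file.path(out, "cells.csv"))
  }

  if (is.null(cells$phenotype)) {
    stop("cell table has no phenotype column and no cube was given")
  }

  # --- sociology -------------------------------------------------------
  graph <- build_graph(cells, roi_obj)
  soc <- summarize_sociology(graph, cells)
  artifacts$edges <- write_edges_csv(graph, file.path(out, "edges.csv"))
  artifacts$sociology <- write_sociology_csv(
    soc, file.path(out, "sociology.csv"), file.path(out, "density.csv"),
    roi_id = config$roi_id)
  artifacts$cell_frequencies <- write_cells_csv(
    cell_frequencies(graph, cells), file.path(out, "cell_frequencies.csv"))

  # --- montecarlo ------------------------------------------------------
  zs <- NULL
  if (isTRUE(config$run_montecarlo)) {
    zs <- sociology_zscores(graph, n_iter = config$n_iter,
                            seed = config$seed, cells = cells)
    artifacts$zscores <- write_zscores_csv(zs, file.path(out, "zscores.csv"),
                                           roi_id = config$roi_id)
  }

  write_provenance(file.path(out, "provenance.json"), inputs = inputs,
                   params = config[setdiff(names(config),
                                           c("cells", "roi"))])
  invisible(list(cells = cells, graph = graph, sociology = soc,
                 zscores = zs, artifacts = artifacts))
}
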