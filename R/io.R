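# Readers and writers for the pipeline's on-disk dialects.
# Conventions: pixel coordinates, origin top-left, x = column, y = row,
# 0-based. CSVs are UTF-8, comma-separated, header row, '.' decimal, floats
# at 9 significant digits. Float TIFFs are stored normalized to [0, 1] with
# the scale factor recorded in the JSON sidecar (the TIFF writer clamps
# samples outside that range), and readers undo the scaling.

sidecar_path <- function(path) paste0(path, ".json")

signif_df <- function(df, digits = 9) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      df[[nm]] <- signif(df[[nm]], digits)
    }
  }
  df
}

#' Write / read a cell table CSV
#' @param cells Cell table data.frame.
#' @param path File path.
#' @return `read_cells_csv` returns the data.frame.
#' @export
write_cells_csv <- function(cells, path) {
  write.csv(signif_df(as.data.frame(cells)), path, row.names = FALSE,
            fileEncoding = "UTF-8", quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cells_csv
#' @export
read_cells_csv <- function(path) {
  read.csv(path, fileEncoding = "UTF-8", stringsAsFactors = FALSE)
}

#' Write a neighbor graph's edge list CSV
#' @param graph A [build_graph()] result.
#' @param path File path.
#' @export
write_edges_csv <- function(graph, path) {
  e <- graph$edges
  names(e) <- c("id_a", "id_b", "shared_edge_len_px")
  write.csv(signif_df(e), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write sociology summary CSVs
#' @param result A [summarize_sociology()] result.
#' @param freq_path,density_path Output CSV paths.
#' @param roi_id Identifier written into the `roi` column.
#' @export
write_sociology_csv <- function(result, freq_path, density_path,
                                roi_id = "roi1") {
  fr <- cbind(roi = roi_id, result$frequencies)
  de <- cbind(roi = roi_id, result$densities)
  write.csv(signif_df(fr), freq_path, row.names = FALSE, quote = FALSE)
  write.csv(signif_df(de), density_path, row.names = FALSE, quote = FALSE)
  invisible(freq_path)
}

#' Write Monte Carlo z-score table CSV
#' @param zscores A [sociology_zscores()] data.frame.
#' @param path File path.
#' @param roi_id Identifier written into the `roi` column.
#' @export
write_zscores_csv <- function(zscores, path, roi_id = "roi1") {
  write.csv(signif_df(cbind(roi = roi_id, zscores)), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read an ROI polygon as GeoJSON (pixel coordinates)
#' @param roi An [roi()] object.
#' @param path File path.
#' @param pixel_spacing_um Pixel size used when reading (stored in the
#'   GeoJSON properties when writing).
#' @export
write_roi_geojson <- function(roi, path) {
  ring <- lapply(c(seq_along(roi$x), 1L),
                 function(i) c(roi$x[i], roi$y[i]))
  gj <- list(type = "Feature",
             properties = list(pixel_spacing_um = roi$pixel_spacing_um),
             geometry = list(type = "Polygon", coordinates = list(ring)))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_geojson
#' @export
read_roi_geojson <- function(path, pixel_spacing_um = NULL) {
  gj <- jsonlite::read_json(path)
  geom <- if (!is.null(gj$geometry)) gj$geometry else gj
  if (is.null(geom$type) || geom$type != "Polygon") {
    stop("expected a GeoJSON Polygon in ", path)
  }
  ring <- geom$coordinates[[1]]
  xy <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  # drop the repeated closing vertex
  if (all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
  if (is.null(pixel_spacing_um)) {
    pixel_spacing_um <- gj$properties$pixel_spacing_um
    if (is.null(pixel_spacing_um)) pixel_spacing_um <- 0.33
  }
  roi(xy[, 1], xy[, 2], pixel_spacing_um = pixel_spacing_um)
}

write_float_tiff <- function(pages, path) {
  mx <- max(1e-300, max(vapply(pages, max, numeric(1))))
  mn <- min(vapply(pages, min, numeric(1)))
  if (mn < 0) stop("float TIFF pages must be non-negative")
  scaled <- lapply(pages, function(p) p / mx)
  suppressWarnings(tiff::writeTIFF(scaled, path, bits.per.sample = 32,
                                   reduce = FALSE))
  mx
}

read_float_tiff <- function(path, scale) {
  pages <- suppressWarnings(tiff::readTIFF(path, all = TRUE))
  lapply(pages, function(p) p * scale)
}

#' Write / read a spectral cube as multi-page TIFF + JSON sidecar
#'
#' One page per band; the sidecar (`<path>.json`) records wavelengths,
#' blank reference, the normalization scale and whether the cube holds
#' optical density.
#'
#' @param cube A [spectral_cube()].
#' @param path TIFF path.
#' @export
write_cube_tiff <- function(cube, path) {
  d <- dim(cube$data)
  pages <- lapply(seq_len(d[3]), function(b) cube$data[, , b])
  if (cube$od) pages <- lapply(pages, function(p) pmax(p, 0))
  scale <- write_float_tiff(pages, path)
  blank <- cube$blank_reference
  meta <- list(wavelengths_nm = cube$wavelengths,
               blank_reference = if (is.array(blank)) NULL else blank,
               scale = scale, od = cube$od, n_clamped = cube$n_clamped)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_cube_tiff
#' @export
read_cube_tiff <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- read_float_tiff(path, meta$scale)
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (b in seq_along(pages)) arr[, , b] <- pages[[b]]
  cube <- spectral_cube(
    if (isTRUE(meta$od)) arr else pmax(arr, .Machine$double.xmin),
    meta$wavelengths_nm,
    blank_reference = meta$blank_reference)
  cube$od <- isTRUE(meta$od)
  cube$n_clamped <- if (!is.null(meta$n_clamped)) as.integer(meta$n_clamped) else 0L
  cube
}

#' Write concentration maps as one float TIFF per stain plus residual
#'
#' @param cmaps A [mcr_als_unmix()] result.
#' @param dir Output directory (created if needed).
#' @return Invisible named vector of file paths; run metadata goes to
#'   `unmix_meta.json`.
#' @export
write_maps_tiff <- function(cmaps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  scales <- list()
  for (s in names(cmaps$maps)) {
    p <- file.path(dir, paste0(s, ".tif"))
    scales[[s]] <- write_float_tiff(list(cmaps$maps[[s]]), p)
    paths[s] <- p
  }
  rp <- file.path(dir, "residual.tif")
  scales[["residual"]] <- write_float_tiff(list(cmaps$residual), rp)
  paths["residual"] <- rp
  jsonlite::write_json(list(stains = names(cmaps$maps), scales = scales,
                            n_iterations = cmaps$n_iterations,
                            converged = cmaps$converged),
                       file.path(dir, "unmix_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname write_maps_tiff
#' @export
read_maps_tiff <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "unmix_meta.json"),
                              simplifyVector = TRUE)
  maps <- setNames(lapply(meta$stains, function(s) {
    read_float_tiff(file.path(dir, paste0(s, ".tif")),
                    meta$scales[[s]])[[1]]
  }), meta$stains)
  resid <- read_float_tiff(file.path(dir, "residual.tif"),
                           meta$scales[["residual"]])[[1]]
  structure(list(maps = maps, residual = resid, spectra = NULL,
                 n_iterations = meta$n_iterations,
                 converged = meta$converged),
            class = "concentration_maps")
}

#' Write / read a label image as 16-bit TIFF + sidecar
#' @param labimg A `label_image`.
#' @param path TIFF path.
#' @export
write_labels_tiff <- function(labimg, path) {
  K <- max(labimg$labels)
  if (K > 65535) stop("more than 65535 labels cannot be stored as 16-bit")
  suppressWarnings(tiff::writeTIFF(labimg$labels / 65535, path,
                                   bits.per.sample = 16, reduce = FALSE))
  jsonlite::write_json(list(n_labels = K,
                            pixel_spacing_um = labimg$pixel_spacing_um),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_labels_tiff
#' @export
read_labels_tiff <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  m <- suppressWarnings(tiff::readTIFF(path))
  structure(list(labels = matrix(as.integer(round(m * 65535)), nrow(m)),
                 pixel_spacing_um = meta$pixel_spacing_um),
            class = "label_image")
}

#' Read / write stain spectra JSON
#'
#' Sidecar dialect: `{"wavelengths_nm": [...], "stains": [{"name": ...,
#' "absorbance": [...]}, ...]}`.
#'
#' @param path File path.
#' @export
read_spectra_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ab <- do.call(rbind, lapply(seq_len(nrow(j$stains)), function(i) {
    as.numeric(j$stains$absorbance[[i]])
  }))
  rownames(ab) <- j$stains$name
  list(wavelengths = as.numeric(j$wavelengths_nm),
       spectra = stain_spectra(ab, j$wavelengths_nm))
}

#' @rdname read_spectra_json
#' @param spectra A [stain_spectra()].
#' @param wavelengths Band wavelengths (nm).
#' @export
write_spectra_json <- function(spectra, wavelengths, path) {
  stains <- lapply(rownames(spectra), function(s) {
    list(name = s, absorbance = as.numeric(unclass(spectra)[s, ]))
  })
  jsonlite::write_json(list(wavelengths_nm = wavelengths, stains = stains),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a provenance sidecar
#'
#' Records package version, timestamp, seeds and md5 hashes of input files
#' next to an output artifact.
#'
#' @param path Output JSON path.
#' @param inputs Character vector of input file paths to hash.
#' @param params List of run parameters (seeds included).
#' @export
write_provenance <- function(path, inputs = character(0), params = list()) {
  hashes <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else list()
  jsonlite::write_json(
    list(package = "cellsociology",
         version = as.character(packageVersion("cellsociology")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         input_md5 = hashes, params = params),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
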