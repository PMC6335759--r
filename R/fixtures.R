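# Synthetic ground-truth generators: labeled point patterns on a jittered
# hexagonal lattice (an idealization of an epithelial sheet), forward-model
# rendering of stained-image cubes, and in-silico cohorts where the outcome
# groups differ only in how immune cells mix into the tumor sheet (so
# density and sociology decouple by construction).

#' Describe a synthetic tissue
#'
#' Cell positions are sites of a hexagonal lattice with Gaussian positional
#' jitter (sd = `jitter_frac` of the spacing), clipped to the ROI. The first
#' named proportion is the background type (tumor in the default panel);
#' the spatial regime controls how the remaining types are placed over the
#' fixed site set:
#' * `uniform` — labels assigned completely at random;
#' * `clustered` — each non-background type occupies the sites nearest a few
#'   random parent sites (a Neyman-Scott-like process over the lattice);
#' * `segregated` — contiguous blocks along x, one per type;
#' * `infiltrated` — a fraction `mixing_fraction` of each non-background
#'   type is scattered uniformly among the tumor sheet, the rest is
#'   clustered; `mixing_fraction` tunes tissue from compartmentalized
#'   (immune cells pooled in stroma-like clusters) to diffusely infiltrated.
#'
#' @param n_cells Number of cells.
#' @param proportions Named numeric vector of phenotype proportions, summing
#'   to 1; the first name is the background type.
#' @param regime One of `"uniform"`, `"clustered"`, `"segregated"`,
#'   `"infiltrated"`.
#' @param roi An [roi()]; by default a square sized to hold `n_cells` at the
#'   given spacing.
#' @param spacing_px Lattice spacing in px (default 30 px, about 10 um at
#'   0.33 um/px — packed epithelium).
#' @param jitter_frac Positional jitter sd as a fraction of the spacing
#'   (default 0.15).
#' @param cluster_size Mean cells per cluster parent (default 15).
#' @param mixing_fraction For the infiltrated regime: fraction of each
#'   immune type scattered uniformly (default 0.5).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return Object of class `tissue_model`.
#' @export
tissue_model <- function(n_cells = 300,
                         proportions = c(UNSTAINED = 0.85, CD3_T = 0.06,
                                         CD3_CD8_T = 0.06, CD79A_B = 0.03),
                         regime = c("uniform", "clustered", "segregated",
                                    "infiltrated"),
                         roi = NULL, spacing_px = 30, jitter_frac = 0.15,
                         cluster_size = 15, mixing_fraction = 0.5,
                         seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(n_cells >= 3, all(proportions >= 0), !is.null(names(proportions)))
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  if (spacing_px < 1) {
    stop("infeasible density: mean nearest-neighbor spacing below 1 px")
  }
  if (is.null(roi)) {
    # hex site density is 2/(sqrt(3) s^2); size the square with 25% slack
    area <- n_cells * sqrt(3) / 2 * spacing_px^2 * 1.25
    side <- ceiling(sqrt(area))
    roi <- rect_roi(0, 0, side, side)
  }
  structure(list(n_cells = n_cells, proportions = proportions,
                 regime = regime, roi = roi, spacing_px = spacing_px,
                 jitter_frac = jitter_frac, cluster_size = cluster_size,
                 mixing_fraction = mixing_fraction, seed = as.integer(seed)),
            class = "tissue_model")
}

hex_sites <- function(roi, spacing, jitter_sd) {
  bb <- roi_bbox(roi)
  dy <- spacing * sqrt(3) / 2
  ys <- seq(bb["ymin"] + spacing / 2, bb["ymax"], by = dy)
  pts <- do.call(rbind, lapply(seq_along(ys), function(r) {
    x0 <- bb["xmin"] + spacing / 2 + (r %% 2) * spacing / 2
    xs <- seq(x0, bb["xmax"], by = spacing)
    cbind(xs, rep(ys[r], length(xs)))
  }))
  pts <- pts + matrix(rnorm(length(pts), sd = jitter_sd), ncol = 2)
  pts[roi_contains(roi, pts[, 1], pts[, 2]), , drop = FALSE]
}

#' Generate a synthetic tissue from a model
#'
#' @param model A [tissue_model()].
#' @return data.frame with `id`, `x`, `y`, `phenotype`, `origin`; the ROI is
#'   attached as attribute `"roi"`. Byte-identical for identical models.
#' @export
generate_tissue <- function(model) {
  stopifnot(inherits(model, "tissue_model"))
  set.seed(model$seed)
  sites <- hex_sites(model$roi, model$spacing_px,
                     model$jitter_frac * model$spacing_px)
  if (nrow(sites) < model$n_cells) {
    stop("ROI too small for ", model$n_cells, " cells at spacing ",
         model$spacing_px, " px (only ", nrow(sites), " sites)")
  }
  sites <- sites[sample.int(nrow(sites), model$n_cells), , drop = FALSE]
  n <- model$n_cells
  types <- names(model$proportions)
  counts <- as.vector(rmultinom(1, n, model$proportions))
  names(counts) <- types

  labels <- rep(types[1], n)
  immune <- types[-1]

  assign_clustered <- function(labels, type, count, pool) {
    # pool: indices still available; occupy sites nearest random parents
    if (count == 0 || length(pool) == 0) return(labels)
    n_par <- max(1, round(count / model$cluster_size))
    par_idx <- pool[sample.int(length(pool), min(n_par, length(pool)))]
    d2 <- rep(Inf, length(pool))
    for (p in par_idx) {
      d2 <- pmin(d2, (sites[pool, 1] - sites[p, 1])^2 +
                     (sites[pool, 2] - sites[p, 2])^2)
    }
    take <- pool[order(d2)[seq_len(min(count, length(pool)))]]
    labels[take] <- type
    labels
  }

  if (model$regime == "uniform") {
    labels <- sample(rep(types, counts))
  } else if (model$regime == "segregated") {
    ord <- order(sites[, 1], sites[, 2])
    labels[ord] <- rep(types, counts)
  } else if (model$regime == "clustered") {
    for (t in immune) {
      pool <- which(labels == types[1])
      labels <- assign_clustered(labels, t, counts[[t]], pool)
    }
  } else { # infiltrated
    f <- model$mixing_fraction
    for (t in immune) {
      ct <- counts[[t]]
      n_mix <- round(f * ct)
      pool <- which(labels == types[1])
      if (n_mix > 0) {
        take <- pool[sample.int(length(pool), min(n_mix, length(pool)))]
        labels[take] <- t
      }
      pool <- which(labels == types[1])
      labels <- assign_clustered(labels, t, ct - n_mix, pool)
    }
  }

  cells <- data.frame(id = seq_len(n), x = sites[, 1], y = sites[, 2],
                      phenotype = labels, origin = "segmented")
  attr(cells, "roi") <- model$roi
  cells
}

#' Render a synthetic stained-image cube from a cell table
#'
#' The forward model of the unmixing stage: ground-truth per-stain
#' concentration maps are painted as Gaussian blobs (a nuclear hematoxylin
#' blob for every cell plus phenotype-specific marker blobs: CD3 for T
#' cells, CD3 and CD8 for cytotoxic T cells, CD79a for B cells), then the
#' transmitted-intensity cube is `blank * 10^-(C . S) ` with optional
#' Gaussian noise of sd `noise_sd` added in the optical-density domain.
#'
#' @param cells Cell table with `x`, `y`, `phenotype` (pixel coordinates,
#'   0-based).
#' @param spectra A [stain_spectra()] whose rows cover the stains used
#'   (default [synthetic_stain_spectra()]).
#' @param wavelengths Band wavelengths (default 420-720 nm by 20).
#' @param dim Image rows and cols; default covers the cells' ROI/bounding
#'   box.
#' @param noise_sd Optical-density noise sd (0 = noiseless).
#' @param nucleus_sigma_px,marker_sigma_px Gaussian blob sds (defaults 4 and
#'   5.5 px; markers are membranous, hence wider).
#' @param amplitude Peak nuclear OD contribution per unit spectrum.
#' @param blank Blank-slide intensity in counts (default 10000).
#' @return List: `cube` (a raw-intensity [spectral_cube()]), `truth` (named
#'   list of ground-truth concentration maps) and `cells`.
#' @export
render_cube <- function(cells, spectra = synthetic_stain_spectra(),
                        wavelengths = seq(420, 720, by = 20), dim = NULL,
                        noise_sd = 0, nucleus_sigma_px = 4,
                        marker_sigma_px = 5.5, amplitude = 1,
                        blank = 10000) {
  stopifnot(ncol(spectra) == length(wavelengths))
  if (is.null(dim)) {
    r <- attr(cells, "roi")
    if (!is.null(r)) {
      bb <- roi_bbox(r)
      dim <- c(ceiling(bb["ymax"]) + 1, ceiling(bb["xmax"]) + 1)
    } else {
      dim <- c(ceiling(max(cells$y)) + 8, ceiling(max(cells$x)) + 8)
    }
  }
  nr <- dim[1]; nc <- dim[2]
  stains <- rownames(spectra)
  truth <- setNames(lapply(stains, function(s) matrix(0, nr, nc)), stains)

  marker_map <- list(CD3_T = "cd3", CD3_CD8_T = c("cd3", "cd8"),
                     CD79A_B = "cd79a")

  paint <- function(m, cx, cy, sigma, amp) {
    # local window of +/- 4 sigma; pixel centers at 0-based coordinates
    r0 <- max(1, floor(cy - 4 * sigma) + 1)
    r1 <- min(nr, ceiling(cy + 4 * sigma) + 1)
    c0 <- max(1, floor(cx - 4 * sigma) + 1)
    c1 <- min(nc, ceiling(cx + 4 * sigma) + 1)
    if (r0 > r1 || c0 > c1) return(m)
    ry <- (r0:r1) - 1; cx_ <- (c0:c1) - 1
    g <- outer(exp(-((ry - cy)^2) / (2 * sigma^2)),
               exp(-((cx_ - cx)^2) / (2 * sigma^2)))
    m[r0:r1, c0:c1] <- m[r0:r1, c0:c1] + amp * g
    m
  }

  for (k in seq_len(nrow(cells))) {
    truth$hematoxylin <- paint(truth$hematoxylin, cells$x[k], cells$y[k],
                               nucleus_sigma_px, amplitude)
    for (s in marker_map[[as.character(cells$phenotype[k])]]) {
      truth[[s]] <- paint(truth[[s]], cells$x[k], cells$y[k],
                          marker_sigma_px, amplitude)
    }
  }

  S <- unclass(spectra)
  od <- array(0, dim = c(nr, nc, length(wavelengths)))
  for (s in stains) {
    for (b in seq_along(wavelengths)) {
      od[, , b] <- od[, , b] + truth[[s]] * S[s, b]
    }
  }
  if (noise_sd > 0) {
    od <- od + array(rnorm(length(od), sd = noise_sd), dim = dim(od))
  }
  raw <- blank * 10^(-od)
  cube <- spectral_cube(raw, wavelengths,
                        blank_reference = rep(blank, length(wavelengths)))
  list(cube = cube, truth = truth, cells = cells)
}

#' Generate an in-silico cohort with a pure-infiltration effect
#'
#' Builds `n_recurrent + n_non_recurrent` patients with `rois_per_patient`
#' tissues each. Both groups share the same cell count and phenotype
#' proportions (so expected densities are matched); they differ only in the
#' infiltrated regime's `mixing_fraction`, i.e. in how immune cells mix
#' into the tumor sheet. This injects a sociology signal (tumor-immune
#' neighbor frequencies) with no density signal.
#'
#' @param n_recurrent,n_non_recurrent Patients per outcome group (defaults
#'   11 and 8).
#' @param rois_per_patient ROIs per patient (default 5).
#' @param mixing Named numeric: mixing fractions per group (defaults
#'   `recurrent = 0.15`, `non_recurrent = 0.85`).
#' @param n_cells Cells per ROI (default 150).
#' @param proportions Phenotype proportions (see [tissue_model()]).
#' @param seed Master seed; per-ROI seeds derive from it.
#' @param ... Further arguments passed to [tissue_model()].
#' @return List with `manifest` (data.frame `patient_id`, `roi_id`,
#'   `outcome`) and `tissues` (named list of cell tables keyed
#'   `"<patient>:<roi>"`).
#' @export
generate_cohort <- function(n_recurrent = 11, n_non_recurrent = 8,
                            rois_per_patient = 5,
                            mixing = c(recurrent = 0.15, non_recurrent = 0.85),
                            n_cells = 150,
                            proportions = c(UNSTAINED = 0.85, CD3_T = 0.06,
                                            CD3_CD8_T = 0.06, CD79A_B = 0.03),
                            seed = 1L, ...) {
  stopifnot(n_recurrent >= 1, n_non_recurrent >= 1)
  set.seed(seed)
  pats <- data.frame(
    patient_id = sprintf("P%02d", seq_len(n_recurrent + n_non_recurrent)),
    outcome = rep(c("recurrent", "non_recurrent"),
                  c(n_recurrent, n_non_recurrent))
  )
  manifest <- do.call(rbind, lapply(seq_len(nrow(pats)), function(i) {
    data.frame(patient_id = pats$patient_id[i],
               roi_id = sprintf("R%d", seq_len(rois_per_patient)),
               outcome = pats$outcome[i])
  }))
  roi_seeds <- sample.int(.Machine$integer.max - 1, nrow(manifest))
  tissues <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- tissue_model(n_cells = n_cells, proportions = proportions,
                      regime = "infiltrated",
                      mixing_fraction = mixing[[manifest$outcome[i]]],
                      seed = roi_seeds[i], ...)
    generate_tissue(m)
  })
  names(tissues) <- paste(manifest$patient_id, manifest$roi_id, sep = ":")
  list(manifest = manifest, tissues = tissues)
}

#' Density and sociology metrics for a generated cohort
#'
#' Runs [build_graph()] and [summarize_sociology()] on every ROI of a
#' [generate_cohort()] result and returns a long [cohort_table()] with two
#' metrics: `density_<neighbor>` (cells/mm^2) and
#' `socio_<focal>_<neighbor>` (mean neighbor frequency of `neighbor` around
#' `focal` cells).
#'
#' @param cohort A [generate_cohort()] result.
#' @param focal,neighbor Phenotypes of the tracked interaction (defaults
#'   `UNSTAINED` tumor cells with `CD3_CD8_T` neighbors).
#' @return A [cohort_table()].
#' @export
cohort_metrics <- function(cohort, focal = "UNSTAINED",
                           neighbor = "CD3_CD8_T") {
  man <- cohort$manifest
  met_d <- paste0("density_", neighbor)
  met_s <- paste0("socio_", focal, "_", neighbor)
  rows <- lapply(seq_len(nrow(man)), function(i) {
    cells <- cohort$tissues[[paste(man$patient_id[i], man$roi_id[i],
                                   sep = ":")]]
    g <- build_graph(cells, attr(cells, "roi"))
    s <- summarize_sociology(g)
    dv <- s$densities$density_mm2[s$densities$phenotype == neighbor]
    fv <- s$frequencies$mean_frequency[s$frequencies$focal == focal &
                                         s$frequencies$neighbor == neighbor]
    data.frame(patient_id = rep(man$patient_id[i], 2),
               roi_id = rep(man$roi_id[i], 2),
               outcome = rep(man$outcome[i], 2),
               metric = c(met_d, met_s),
               value = c(if (length(dv)) dv else 0,
                         if (length(fv)) fv else NA_real_))
  })
  df <- do.call(rbind, rows)
  cohort_table(df$patient_id, df$roi_id, df$outcome, df$metric, df$value)
}
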