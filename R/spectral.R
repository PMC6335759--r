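# Spectral unmixing of multichannel brightfield stacks into per-stain
# concentration maps under the Beer-Lambert model: after conversion to
# optical density, each pixel's spectrum is a non-negative linear
# combination of the stain absorbance spectra plus noise. Concentrations are
# not required to sum to one (no additivity constraint).

#' Construct a hyperspectral image cube
#'
#' @param data 3-D numeric array, rows x cols x bands, raw transmitted
#'   intensity in arbitrary camera units.
#' @param wavelengths Numeric vector of band wavelengths (nm), strictly
#'   increasing, one per band.
#' @param blank_reference Per-band blank-slide intensity: a numeric vector
#'   of length `length(wavelengths)`, or a rows x cols x bands array.
#' @return Object of class `spectral_cube`.
#' @export
spectral_cube <- function(data, wavelengths, blank_reference = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (dim(data)[3] != length(wavelengths)) {
    stop("band count (", dim(data)[3], ") must equal wavelength count (",
         length(wavelengths), ")")
  }
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  if (!is.null(blank_reference)) {
    if (is.array(blank_reference) && length(dim(blank_reference)) == 3) {
      stopifnot(all(dim(blank_reference) == dim(data)))
    } else {
      stopifnot(length(blank_reference) == length(wavelengths))
    }
    if (any(blank_reference <= 0)) stop("blank reference must be positive")
  }
  structure(list(data = data, wavelengths = as.numeric(wavelengths),
                 blank_reference = blank_reference, od = FALSE,
                 n_clamped = 0L),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Spectral cube: %d x %d px, %d bands (%g-%g nm), %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              if (x$od) "optical density" else "raw intensity"))
  invisible(x)
}

#' Stain absorbance spectra
#'
#' Row-normalizes each stain's absorbance to unit maximum; the scale then
#' lives entirely in the concentrations, removing the scale indeterminacy of
#' the bilinear model.
#'
#' @param absorbance Numeric matrix, stains x bands, non-negative, with
#'   stain names as rownames.
#' @param wavelengths Optional wavelengths (nm) checked for length.
#' @return Object of class `stain_spectra` (the normalized matrix).
#' @export
stain_spectra <- function(absorbance, wavelengths = NULL) {
  stopifnot(is.matrix(absorbance), !is.null(rownames(absorbance)))
  if (any(absorbance < 0)) stop("absorbance coefficients must be non-negative")
  if (!is.null(wavelengths) && ncol(absorbance) != length(wavelengths)) {
    stop("spectra have ", ncol(absorbance), " bands but ",
         length(wavelengths), " wavelengths were given")
  }
  mx <- apply(absorbance, 1, max)
  if (any(mx == 0)) stop("stain(s) with all-zero spectrum: ",
                         paste(rownames(absorbance)[mx == 0], collapse = ", "))
  structure(absorbance / mx, class = c("stain_spectra", "matrix"))
}

#' Synthetic default absorbance spectra for the 4-stain panel
#'
#' Gaussian-shaped absorbance bands loosely imitating hematoxylin and the
#' three chromogens of a CD3/CD8/CD79a panel (Ferangi Blue, DAB, Warp Red).
#' These are synthetic stand-ins for instrument-measured spectra, intended
#' for simulation and testing; real analyses should supply measured spectra.
#'
#' @param wavelengths Band wavelengths in nm (default 420-720 nm in 20 nm
#'   steps, a 16-band acquisition).
#' @return A [stain_spectra()] object with rows `hematoxylin`, `cd3`, `cd8`,
#'   `cd79a`.
#' @export
synthetic_stain_spectra <- function(wavelengths = seq(420, 720, by = 20)) {
  peak <- function(center, width, floor = 0.02) {
    exp(-0.5 * ((wavelengths - center) / width)^2) + floor
  }
  ab <- rbind(
    hematoxylin = peak(590, 55),          # blue-purple nuclear stain
    cd3         = peak(650, 45),          # blue chromogen (absorbs red)
    cd8         = 0.6 * peak(460, 90) + 0.4 * peak(560, 80), # brown, broad
    cd79a       = peak(520, 40)           # red chromogen (absorbs green)
  )
  stain_spectra(ab, wavelengths)
}

#' Convert a raw intensity cube to optical density
#'
#' `OD(pixel, band) = log10(blank(band) / intensity(pixel, band))`.
#' Intensities below `floor` (counts) are clamped up to `floor` before the
#' log; the number of clamped pixels is recorded on the result and reported
#' as a warning.
#'
#' @param cube A [spectral_cube()] with a blank reference.
#' @param floor Intensity floor in counts (default 1).
#' @return A `spectral_cube` holding OD values (`od = TRUE`, blank retained),
#'   with `n_clamped` set.
#' @export
to_optical_density <- function(cube, floor = 1) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (cube$od) return(cube)
  if (is.null(cube$blank_reference)) {
    stop("configuration error: no blank reference on the cube")
  }
  raw <- cube$data
  n_clamped <- sum(raw < floor)
  if (n_clamped > 0) {
    warning(n_clamped, " intensity value(s) below the floor of ", floor,
            " counts were clamped")
    raw[raw < floor] <- floor
  }
  blank <- cube$blank_reference
  if (!is.array(blank) || length(dim(blank)) != 3) {
    blank <- aperm(array(blank, dim = dim(raw)[c(3, 1, 2)]), c(2, 3, 1))
  }
  od <- log10(blank / raw)
  out <- cube
  out$data <- od
  out$od <- TRUE
  out$n_clamped <- as.integer(n_clamped)
  out
}

# flatten cube to (npixels x nbands); inverse handled by dim<-
cube_matrix <- function(cube) {
  d <- dim(cube$data)
  matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
}

#' Unmix an optical-density cube into per-stain concentration maps
#'
#' Solves, for every pixel, the non-negative least-squares problem
#' `min ||od - c %*% S||^2, c >= 0` with stain spectra `S` fixed (the
#' default), or alternates concentration and spectra updates under
#' non-negativity (`refine_spectra = TRUE`), with the spectra re-normalized
#' to unit maximum after each update. Concentrations are never normalized to
#' sum to one.
#'
#' @param od A [spectral_cube()] in optical density (see
#'   [to_optical_density()]).
#' @param spectra A [stain_spectra()] object (rows = stains).
#' @param max_iter Maximum alternating iterations in refine mode.
#' @param tol Convergence tolerance on the relative change of the residual
#'   norm (refine mode); must be > 0.
#' @param refine_spectra If TRUE, refine the spectra too (full alternating
#'   least squares); the default keeps them fixed, which makes the solve
#'   direct and deterministic.
#' @return Object of class `concentration_maps`: list with `maps` (named
#'   list of 2-D non-negative arrays, one per stain), `residual` (2-D
#'   per-pixel residual norm), `spectra` (as used in the final solve),
#'   `n_iterations`, `converged`.
#' @export
mcr_als_unmix <- function(od, spectra, max_iter = 50, tol = 1e-8,
                          refine_spectra = FALSE) {
  stopifnot(inherits(od, "spectral_cube"))
  if (!od$od) stop("cube must be in optical density; run to_optical_density() first")
  if (tol <= 0) stop("parameter error: tol must be > 0")
  S <- unclass(spectra)
  if (ncol(S) != dim(od$data)[3]) {
    stop("spectra have ", ncol(S), " bands but the cube has ", dim(od$data)[3])
  }
  if (!all(is.finite(od$data))) stop("cube contains non-finite values")
  check_spectra_rank(S)

  Y <- cube_matrix(od)
  d <- dim(od$data)

  C <- nnls_rows(Y, S)
  res_norm <- sqrt(sum((Y - C %*% S)^2))
  n_iter <- 1L
  converged <- TRUE

  if (refine_spectra) {
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      # spectra step: bands separate into NNLS solves on the current C;
      # stains with no mass anywhere keep their previous spectrum (their
      # spectrum is unidentifiable from this image)
      present <- colSums(C) > 0
      S_new <- S
      if (any(present)) {
        S_new[present, ] <- t(nnls_rows(t(Y), t(C[, present, drop = FALSE])))
      }
      mx <- apply(S_new, 1, max)
      if (any(mx == 0)) break # a stain vanished; keep previous estimate
      S_new <- S_new / mx
      C <- nnls_rows(Y, S_new)
      S <- S_new
      new_norm <- sqrt(sum((Y - C %*% S)^2))
      n_iter <- it + 1L
      # converged when the relative residual change is below tol, or the
      # fit is essentially exact relative to the data norm
      if (abs(res_norm - new_norm) / max(res_norm, 1e-300) < tol ||
          new_norm <= 1e-10 * sqrt(sum(Y^2))) {
        res_norm <- new_norm
        converged <- TRUE
        break
      }
      res_norm <- new_norm
    }
    rownames(S) <- rownames(spectra)
  }

  resid <- sqrt(rowSums((Y - C %*% S)^2))
  maps <- lapply(seq_len(nrow(S)), function(k) {
    m <- C[, k]
    dim(m) <- d[1:2]
    m
  })
  names(maps) <- rownames(S)

  structure(list(maps = maps,
                 residual = array(resid, dim = d[1:2]),
                 spectra = stain_spectra(S),
                 n_iterations = n_iter, converged = converged),
            class = "concentration_maps")
}

#' @export
print.concentration_maps <- function(x, ...) {
  d <- dim(x$residual)
  cat(sprintf("Concentration maps: %s (%d x %d px), %d iteration(s), %s\n",
              paste(names(x$maps), collapse = ", "), d[1], d[2],
              x$n_iterations, if (x$converged) "converged" else "not converged"))
  cat(sprintf("Mean residual norm per pixel: %.3g\n", mean(x$residual)))
  invisible(x)
}

# error naming the most collinear stain pair when the spectra matrix is
# numerically rank-deficient
check_spectra_rank <- function(S) {
  if (qr(t(S))$rank < nrow(S)) {
    gram <- S %*% t(S)
    nrm <- sqrt(diag(gram))
    cos <- gram / outer(nrm, nrm)
    diag(cos) <- 0
    idx <- which(cos == max(cos), arr.ind = TRUE)[1, ]
    stop("stain spectra are rank deficient; '", rownames(S)[idx[1]],
         "' and '", rownames(S)[idx[2]], "' are collinear")
  }
}

# Row-wise non-negative least squares: solve min ||Y[p,] - c S|| with c >= 0
# for every row p. The unconstrained solution is computed in one matrix
# product; only rows with negative entries fall back to the active-set
# solver (pracma::lsqnonneg).
nnls_rows <- function(Y, S) {
  St <- t(S)
  G <- S %*% St
  Ginv <- tryCatch(solve(G), error = function(e) pracma::pinv(G))
  C <- Y %*% St %*% Ginv
  bad <- which(apply(C, 1, function(r) any(r < -1e-10)))
  for (p in bad) {
    C[p, ] <- tryCatch(pracma::lsqnonneg(St, Y[p, ])$x,
                       error = function(e) pmax(C[p, ], 0))
  }
  C[C < 0] <- 0
  C
}
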