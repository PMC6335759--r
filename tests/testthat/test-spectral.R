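wl <- seq(420, 720, by = 20)

test_that("optical density definition and clamping", {
  blank <- rep(1000, 16)
  d <- array(1000, dim = c(4, 4, 16))
  cube <- spectral_cube(d, wl, blank)
  od <- to_optical_density(cube)
  expect_equal(od$data, array(0, dim = dim(d)))

  d2 <- d; d2[2, 2, 5] <- 100 # blank/10 at one band
  od2 <- to_optical_density(spectral_cube(d2, wl, blank))
  expect_equal(od2$data[2, 2, 5], 1.0)

  d3 <- d; d3[1, 1, 1] <- 0.2 # below the 1-count floor
  expect_warning(od3 <- to_optical_density(spectral_cube(d3, wl, blank)),
                 "clamped")
  expect_equal(od3$n_clamped, 1L)
  expect_error(to_optical_density(spectral_cube(d, wl)), "blank")
})

test_that("cube and spectra constructors enforce their invariants", {
  expect_error(spectral_cube(array(1, c(2, 2, 3)), c(420, 440)), "band count")
  expect_error(spectral_cube(array(1, c(2, 2, 2)), c(440, 420)), "increasing")
  ab <- rbind(a = c(1, 2, 0), b = c(0, 1, 1))
  sp <- stain_spectra(ab)
  expect_equal(unname(apply(unclass(sp), 1, max)), c(1, 1))
  expect_error(stain_spectra(rbind(a = c(-1, 1, 0))), "non-negative")
})

test_that("a forward-modelled cube round-trips: OD equals C*S, unmixing recovers C", {
  sp <- synthetic_stain_spectra(wl)
  set.seed(41)
  nr <- 24; nc <- 24
  S <- unclass(sp)
  C_true <- array(runif(nr * nc * 4, 0, 1.5), dim = c(nr, nc, 4))
  C_true[C_true < 0.3] <- 0 # sparse stains
  od_true <- array(0, dim = c(nr, nc, 16))
  for (k in 1:4) for (b in 1:16) {
    od_true[, , b] <- od_true[, , b] + C_true[, , k] * S[k, b]
  }
  blank <- 1e5 # deep well depth so no pixel hits the intensity floor
  raw <- blank * 10^(-od_true)
  cube <- spectral_cube(raw, wl, rep(blank, 16))
  od <- to_optical_density(cube)
  expect_equal(od$data, od_true, tolerance = 1e-12)

  cm <- mcr_als_unmix(od, sp)
  for (k in 1:4) {
    expect_lt(max(abs(cm$maps[[k]] - C_true[, , k])), 1e-6)
  }
  expect_true(all(unlist(cm$maps) >= 0))
  expect_lt(max(cm$residual), 1e-8)
})

test_that("a pure pixel yields the exact single-stain concentration", {
  sp <- synthetic_stain_spectra(wl)
  od_vec <- 2.0 * unclass(sp)["cd3", ]
  od <- spectral_cube(array(od_vec, c(1, 1, 16)), wl, rep(1, 16))
  od$od <- TRUE
  cm <- mcr_als_unmix(od, sp)
  expect_equal(cm$maps$cd3[1, 1], 2.0, tolerance = 1e-9)
  expect_equal(cm$maps$hematoxylin[1, 1], 0, tolerance = 1e-9)
  expect_equal(cm$residual[1, 1], 0, tolerance = 1e-9)
})

test_that("noisy cubes are recovered within 3 sigma RMSE per stain", {
  sp <- synthetic_stain_spectra(wl)
  m <- tissue_model(n_cells = 25, seed = 10, spacing_px = 30)
  cells <- generate_tissue(m)
  clean <- render_cube(cells, sp, wl, noise_sd = 0)
  max_od <- max(sapply(names(clean$truth), function(s) {
    max(clean$truth[[s]])
  }))
  sigma <- 0.01 * max_od
  for (draw in 1:10) {
    set.seed(100 + draw)
    noisy <- render_cube(cells, sp, wl, noise_sd = sigma)
    cm <- mcr_als_unmix(to_optical_density(noisy$cube), sp)
    for (s in names(clean$truth)) {
      rmse <- sqrt(mean((cm$maps[[s]] - clean$truth[[s]])^2))
      expect_lt(rmse, 3 * sigma)
    }
  }
})

test_that("per-pixel solutions match the support-enumeration NNLS oracle", {
  sp <- synthetic_stain_spectra(wl)
  S <- unclass(sp)
  set.seed(77)
  od_px <- matrix(0, 16, 16) # 16 pixels as a 4x4 image
  for (p in 1:16) {
    c_true <- pmax(rnorm(4, 0.3, 0.8), 0)
    od_px[p, ] <- c_true %*% S + rnorm(16, sd = 0.05) # noise forces NNLS
  }
  od <- spectral_cube(array(od_px, c(4, 4, 16)), wl, rep(1, 16))
  od$od <- TRUE
  cm <- mcr_als_unmix(od, sp)
  for (p in 1:16) {
    expected <- oracle_nnls(t(S), od_px[p, ])
    got <- sapply(cm$maps, function(m) m[p])
    expect_equal(unname(got), expected, tolerance = 1e-6)
  }
})

test_that("concentrations scale with OD and are never renormalized", {
  sp <- synthetic_stain_spectra(wl)
  set.seed(9)
  od_dat <- array(abs(rnorm(6 * 6 * 16, 0.5, 0.3)), c(6, 6, 16))
  od <- spectral_cube(od_dat, wl, rep(1, 16)); od$od <- TRUE
  cm1 <- mcr_als_unmix(od, sp)
  od2 <- od; od2$data <- od$data * 4.5
  cm2 <- mcr_als_unmix(od2, sp)
  for (s in names(cm1$maps)) {
    expect_equal(cm2$maps[[s]], 4.5 * cm1$maps[[s]], tolerance = 1e-8)
  }
  # per-pixel sums are unconstrained (not forced to 1)
  sums <- Reduce(`+`, cm1$maps)
  expect_gt(max(abs(sums - 1)), 0.1)
})

test_that("rank-deficient spectra are rejected naming the collinear pair", {
  ab <- rbind(hematoxylin = c(1, 2, 3, 1), cd3 = c(2, 4, 6, 2),
              cd8 = c(1, 0, 0, 1))
  sp <- stain_spectra(ab)
  od <- spectral_cube(array(0.5, c(2, 2, 4)), c(420, 440, 460, 480), rep(1, 4))
  od$od <- TRUE
  err <- tryCatch(mcr_als_unmix(od, sp), error = conditionMessage)
  expect_match(err, "hematoxylin")
  expect_match(err, "cd3")
  expect_error(mcr_als_unmix(od, stain_spectra(ab[c(1, 3), ]), tol = 0),
               "tol")
})

test_that("spectra refinement recovers concentrations from perturbed spectra", {
  sp <- synthetic_stain_spectra(wl)
  m <- tissue_model(n_cells = 15, seed = 14, spacing_px = 32)
  cells <- generate_tissue(m)
  rc <- render_cube(cells, sp, wl)
  od <- to_optical_density(rc$cube)
  S0 <- unclass(sp) * matrix(runif(64, 0.9, 1.1), 4, 16) # mis-specified start
  cm <- mcr_als_unmix(od, stain_spectra(S0), refine_spectra = TRUE,
                      max_iter = 200, tol = 1e-10)
  expect_true(cm$n_iterations > 1)
  expect_true(cm$converged)
  # alternating updates monotonically improve the model fit relative to
  # keeping the mis-specified spectra fixed
  fit0 <- mean(mcr_als_unmix(od, stain_spectra(S0))$residual)
  expect_lt(mean(cm$residual), fit0)
})
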