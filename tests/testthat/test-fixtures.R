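test_that("tissue generation is deterministic and respects its contract", {
  m <- tissue_model(n_cells = 200, seed = 42)
  t1 <- generate_tissue(m)
  t2 <- generate_tissue(m)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 200)
  r <- attr(t1, "roi")
  expect_true(all(roi_contains(r, t1$x, t1$y)))
  # counts match proportions within multinomial noise (4 sd)
  tab <- table(t1$phenotype)
  expect_lt(abs(tab[["UNSTAINED"]] - 170), 4 * sqrt(200 * 0.85 * 0.15))
  expect_error(tissue_model(spacing_px = 0.5), "infeasible")
  expect_error(generate_tissue(tissue_model(n_cells = 5000,
                                            roi = rect_roi(0, 0, 100, 100))),
               "too small")
})

test_that("single-phenotype tissue gives homogeneous sociology downstream", {
  m <- tissue_model(n_cells = 80, proportions = c(tumor = 1), seed = 2)
  cells <- generate_tissue(m)
  g <- build_graph(cells, attr(cells, "roi"))
  s <- summarize_sociology(g)
  expect_equal(s$frequencies$mean_frequency, 1)
})

test_that("segregated tissue produces strong cross-type avoidance downstream", {
  m <- tissue_model(n_cells = 250, proportions = c(A = 0.5, B = 0.5),
                    regime = "segregated", seed = 6)
  cells <- generate_tissue(m)
  g <- build_graph(cells, attr(cells, "roi"))
  expect_lt(permutation_test(g, "A", "B", n_iter = 300, seed = 1)$z, -3)
})

test_that("mixing fraction moves tumor-immune neighbor frequency, not density", {
  mk <- function(f, seed) {
    m <- tissue_model(n_cells = 250, regime = "infiltrated",
                      mixing_fraction = f, seed = seed)
    cells <- generate_tissue(m)
    g <- build_graph(cells, attr(cells, "roi"))
    s <- summarize_sociology(g)
    c(freq = s$frequencies$mean_frequency[s$frequencies$focal == "UNSTAINED" &
                                            s$frequencies$neighbor == "CD3_CD8_T"],
      dens = s$densities$density_mm2[s$densities$phenotype == "CD3_CD8_T"])
  }
  lo <- sapply(1:5, function(s) mk(0.1, 100 + s))
  hi <- sapply(1:5, function(s) mk(0.9, 200 + s))
  expect_gt(mean(hi["freq", ]), 2 * mean(lo["freq", ]))
  # densities are statistically matched: same expected count either way
  expect_lt(abs(mean(hi["dens", ]) - mean(lo["dens", ])),
            0.5 * mean(lo["dens", ]))
})

test_that("rendered cubes invert end-to-end for a single cell", {
  cells <- data.frame(id = 1, x = 25, y = 25, phenotype = "CD3_T")
  rc <- render_cube(cells, dim = c(50, 50))
  cm <- mcr_als_unmix(to_optical_density(rc$cube), synthetic_stain_spectra())
  seg <- segment_nuclei(cm$maps$hematoxylin)
  expect_equal(max(seg$labels), 1)
  ci <- integrate_intensity(seg, cm)
  th <- threshold_set(c(cd3 = 1, cd8 = 1, cd79a = 1))
  out <- phenotype_cells(ci, th)
  expect_equal(out$phenotype, "CD3_T")
})

test_that("a 30-cell rendered tissue is segmented into exactly 30 nuclei", {
  m <- tissue_model(n_cells = 30, seed = 12, spacing_px = 34)
  cells <- generate_tissue(m)
  rc <- render_cube(cells)
  cm <- mcr_als_unmix(to_optical_density(rc$cube), synthetic_stain_spectra())
  seg <- segment_nuclei(cm$maps$hematoxylin)
  expect_equal(max(seg$labels), 30)
})

test_that("superimposed T and B blobs drive one conflict split downstream", {
  cells <- data.frame(id = 1:2, x = c(30, 34), y = c(30, 30),
                      phenotype = c("CD3_T", "CD79A_B"))
  rc <- render_cube(cells, dim = c(60, 60), nucleus_sigma_px = 4)
  cm <- mcr_als_unmix(to_optical_density(rc$cube), synthetic_stain_spectra())
  seg <- segment_nuclei(cm$maps$hematoxylin)
  expect_equal(max(seg$labels), 1) # merged into one nucleus
  ci <- integrate_intensity(seg, cm)
  th <- threshold_set(c(cd3 = 5, cd8 = 5, cd79a = 5))
  out <- phenotype_cells(ci, th)
  expect_equal(nrow(out), 2)
  expect_setequal(out$phenotype, c("CD3_T", "CD79A_B"))
  expect_equal(sum(out$origin == "split_added"), 1)
})

test_that("cohort bookkeeping: 11 vs 8 patients x 5 ROIs gives 95 rows", {
  co <- generate_cohort(n_recurrent = 11, n_non_recurrent = 8,
                        rois_per_patient = 5, n_cells = 60, seed = 3)
  expect_equal(nrow(co$manifest), 95)
  expect_equal(length(co$tissues), 95)
  expect_equal(sum(co$manifest$outcome == "recurrent"), 55)
  met <- cohort_metrics(co)
  expect_equal(nrow(met), 190) # two metrics per ROI
  # determinism
  co2 <- generate_cohort(n_recurrent = 11, n_non_recurrent = 8,
                         rois_per_patient = 5, n_cells = 60, seed = 3)
  expect_identical(co$tissues, co2$tissues)
})

test_that("null cohorts give approximately uniform rank-sum p-values", {
  # no group effect: both groups drawn with the same mixing fraction
  ps <- sapply(1:60, function(r) {
    co <- generate_cohort(n_recurrent = 4, n_non_recurrent = 4,
                          rois_per_patient = 2, n_cells = 60,
                          mixing = c(recurrent = 0.5, non_recurrent = 0.5),
                          seed = 7000 + r)
    compare_groups(cohort_metrics(co), "socio_UNSTAINED_CD3_CD8_T")$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})
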