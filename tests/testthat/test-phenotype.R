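# small synthetic label image + maps used across phenotyping tests
phenotype_fixture <- function() {
  lab <- matrix(0L, 40, 60)
  lab[5:14, 5:14] <- 1L   # 100 px
  lab[5:14, 30:39] <- 2L
  lab[25:34, 5:14] <- 3L
  labimg <- structure(list(labels = lab, pixel_spacing_um = 0.33),
                      class = "label_image")
  zero <- matrix(0, 40, 60)
  maps <- list(hematoxylin = zero + 0.1, cd3 = zero, cd8 = zero, cd79a = zero)
  maps$cd3[5:14, 5:14] <- 0.5
  maps$cd3[5:14, 30:39] <- 0.6
  maps$cd8[5:14, 30:39] <- 0.7
  maps$cd79a[25:34, 5:14] <- 0.4
  list(labimg = labimg, maps = maps)
}

test_that("intensity integration sums concentration over the nucleus", {
  fx <- phenotype_fixture()
  # with no dilation ring the integral is the exact mask sum
  cells <- integrate_intensity(fx$labimg, fx$maps, ring_px = 0)
  expect_equal(cells$I_cd3[1], 100 * 0.5)
  expect_equal(cells$I_cd8[2], 100 * 0.7)
  expect_equal(cells$I_cd79a[3], 100 * 0.4)
  expect_equal(cells$I_cd79a[1], 0)
  expect_equal(cells$area_px, rep(100L, 3))
  # all-zero map integrates to zero everywhere
  expect_true(all(integrate_intensity(fx$labimg,
    list(m = matrix(0, 40, 60)), ring_px = 0)$I_m == 0))
  # a 2-px ring adds surrounding signal monotonically
  cells_ring <- integrate_intensity(fx$labimg, fx$maps, ring_px = 2)
  expect_true(all(cells_ring$I_hematoxylin >= 0))
  expect_gte(cells_ring$I_cd3[1], cells$I_cd3[1])
  expect_error(integrate_intensity(fx$labimg, list(m = matrix(0, 5, 5))),
               "shape mismatch")
})

test_that("the decision tree has exactly 8 leaves covering all sign patterns", {
  leaves <- decision_tree_leaves()
  expect_length(leaves, 8)
  expect_equal(length(unique(names(leaves))), 8)
  # enumeration through classify_cells produces all 8 raw groups
  grid <- expand.grid(cd3 = c(0, 10), cd8 = c(0, 10), cd79a = c(0, 10))
  cells <- data.frame(id = 1:8, x = 1:8, y = 1:8,
                      I_cd3 = grid$cd3, I_cd8 = grid$cd8, I_cd79a = grid$cd79a)
  th <- threshold_set(c(cd3 = 5, cd8 = 5, cd79a = 5))
  cl <- classify_cells(cells, th)
  expect_equal(sort(unique(cl$raw_group)), sort(names(leaves)))
})

test_that("leaf-to-phenotype mapping follows the lineage rules", {
  th <- threshold_set(c(cd3 = 5, cd8 = 5, cd79a = 5))
  mk <- function(cd3, cd8, cd79a) {
    classify_cells(data.frame(id = 1, x = 0, y = 0, I_cd3 = cd3,
                              I_cd8 = cd8, I_cd79a = cd79a), th)$phenotype
  }
  expect_equal(mk(10, 10, 0), "CD3_CD8_T")
  expect_equal(mk(10, 0, 0), "CD3_T")
  expect_equal(mk(0, 0, 10), "CD79A_B")
  expect_equal(mk(0, 0, 0), "UNSTAINED")
  expect_equal(mk(0, 10, 0), "UNSTAINED")  # CD3-CD8+ returned to unstained
  expect_equal(mk(0, 10, 10), "UNSTAINED") # CD3-CD8+CD79a+ likewise
  expect_equal(mk(10, 0, 10), "CONFLICT")
  expect_equal(mk(10, 10, 10), "CONFLICT")
  # inverted legacy scale flips every call
  th_inv <- threshold_set(c(cd3 = 5, cd8 = 5, cd79a = 5), "below")
  cl <- classify_cells(data.frame(id = 1, x = 0, y = 0, I_cd3 = 1,
                                  I_cd8 = 10, I_cd79a = 10), th_inv)
  expect_equal(cl$raw_group, "CD3+CD8-CD79a-")
  expect_error(classify_cells(data.frame(id = 1, I_cd3 = 1), th), "I_cd8")
  expect_error(threshold_set(c(cd3 = 1, cd8 = 1)), "cd79a")
})

test_that("overlapping T/B conflicts are split into two cells", {
  # one nucleus whose CD3 mass sits left and CD79a mass sits right
  lab <- matrix(0L, 30, 30); lab[10:19, 8:21] <- 1L
  labimg <- structure(list(labels = lab, pixel_spacing_um = 0.33),
                      class = "label_image")
  zero <- matrix(0, 30, 30)
  maps <- list(hematoxylin = zero + 0.2, cd3 = zero, cd8 = zero, cd79a = zero)
  maps$cd3[10:19, 8:13] <- 1
  maps$cd79a[10:19, 16:21] <- 0.8
  cells <- integrate_intensity(labimg, maps, ring_px = 0)
  th <- threshold_set(c(cd3 = 1, cd8 = 1, cd79a = 1))
  out <- phenotype_cells(cells, th)
  expect_equal(nrow(out), 2) # split added exactly one cell
  expect_setequal(out$phenotype, c("CD3_T", "CD79A_B"))
  added <- out[out$origin == "split_added", ]
  expect_equal(added$parent_id, out$id[out$origin == "segmented"])
  expect_gt(added$x, out$x[out$origin == "segmented"]) # placed at CD79a mass
  # CD8 status carries to the T half of a triple-positive conflict
  maps$cd8[10:19, 8:13] <- 1
  cells3 <- integrate_intensity(labimg, maps, ring_px = 0)
  out3 <- phenotype_cells(cells3, th)
  expect_setequal(out3$phenotype, c("CD3_CD8_T", "CD79A_B"))
})

test_that("coincident-stain conflicts are excluded, not split", {
  lab <- matrix(0L, 30, 30); lab[10:19, 10:19] <- 1L
  labimg <- structure(list(labels = lab, pixel_spacing_um = 0.33),
                      class = "label_image")
  zero <- matrix(0, 30, 30)
  maps <- list(hematoxylin = zero + 0.2, cd3 = zero, cd8 = zero, cd79a = zero)
  maps$cd3[10:19, 10:19] <- 1
  maps$cd79a[10:19, 10:19] <- 0.8 # same footprint: centroids coincide
  cells <- integrate_intensity(labimg, maps, ring_px = 0)
  th <- threshold_set(c(cd3 = 1, cd8 = 1, cd79a = 1))
  out <- phenotype_cells(cells, th)
  expect_equal(nrow(out), 1)
  expect_equal(out$phenotype, "EXCLUDED")
})

test_that("non-conflicted cells are conserved and thresholds act monotonically", {
  set.seed(31)
  n <- 60
  cells <- data.frame(id = 1:n, x = runif(n, 0, 100), y = runif(n, 0, 100),
                      I_cd3 = rexp(n, 1 / 20), I_cd8 = rexp(n, 1 / 20),
                      I_cd79a = 0) # no conflicts possible
  th1 <- threshold_set(c(cd3 = 30, cd8 = 20, cd79a = 10))
  out1 <- phenotype_cells(cells, th1)
  expect_equal(nrow(out1), n)
  expect_identical(out1$id, cells$id)
  # relaxing the cd3 threshold never loses positives
  th2 <- threshold_set(c(cd3 = 15, cd8 = 20, cd79a = 10))
  out2 <- phenotype_cells(cells, th2)
  expect_gte(sum(out2$pos_cd3), sum(out1$pos_cd3))
  # determinism: identical inputs give identical phenotypes
  expect_identical(out1$phenotype, phenotype_cells(cells, th1)$phenotype)
})

test_that("automatic thresholds separate a clearly bimodal marker", {
  set.seed(5)
  cells <- data.frame(I_cd3 = c(rnorm(80, 5, 1), rnorm(20, 60, 5)),
                      I_cd8 = rnorm(100, 5, 1),
                      I_cd79a = c(rnorm(90, 2, 0.5), rnorm(10, 40, 3)))
  th <- auto_thresholds(cells)
  expect_s3_class(th, "threshold_set")
  # the automatic threshold separates the two modes perfectly: exactly the
  # 20 bright cells are called positive
  expect_equal(sum(cells$I_cd3 > th$thresholds[["cd3"]]), 20)
  expect_equal(sum(cells$I_cd79a > th$thresholds[["cd79a"]]), 10)
})
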