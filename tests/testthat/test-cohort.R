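make_cohort <- function(values_by_patient, outcomes, metric = "m") {
  rows <- do.call(rbind, lapply(names(values_by_patient), function(p) {
    v <- values_by_patient[[p]]
    data.frame(patient_id = p, roi_id = sprintf("R%d", seq_along(v)),
               outcome = outcomes[[p]], metric = metric, value = v)
  }))
  cohort_table(rows$patient_id, rows$roi_id, rows$outcome, rows$metric,
               rows$value)
}

test_that("rank-sum comparison handles the textbook cases", {
  co <- make_cohort(list(P1 = c(1, 2, 3), P2 = c(1, 2, 3)),
                    c(P1 = "recurrent", P2 = "non_recurrent"))
  expect_equal(compare_groups(co, "m")$p_value, 1.0)

  co2 <- make_cohort(list(P1 = c(1, 2, 3), P2 = c(10, 11, 12)),
                     c(P1 = "recurrent", P2 = "non_recurrent"))
  expect_equal(compare_groups(co2, "m")$p_value, 0.1) # exact, 3 vs 3 separation

  expect_error(compare_groups(co, "nope"), "no rows")
})

test_that("rank-sum p-values match exhaustive enumeration for small groups", {
  set.seed(12)
  for (rep in 1:8) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    v1 <- round(runif(n1, 0, 100), 3) # continuous, ties negligible
    v2 <- round(runif(n2, 0, 100) + 20, 3)
    co <- make_cohort(list(P1 = v1, P2 = v2),
                      c(P1 = "recurrent", P2 = "non_recurrent"))
    expect_equal(compare_groups(co, "m")$p_value, oracle_ranksum_p(v2, v1),
                 tolerance = 1e-12)
  }
})

test_that("rank-sum test has power against a 2-SD shift at n = 11 vs 8", {
  set.seed(4)
  rej <- mean(replicate(1000, {
    v1 <- rnorm(11); v2 <- rnorm(8, mean = 2)
    suppressWarnings(wilcox.test(v1, v2)$p.value) < 0.05
  }))
  expect_gt(rej, 0.8)
})

bench_cohort <- function(soc_r, soc_nr, den_r, den_nr, n_rois = 5) {
  # 4 patients; per-ROI constant values per patient
  pats <- c(A = "recurrent", B = "recurrent",
            C = "non_recurrent", D = "non_recurrent")
  vals <- list(A = soc_r[1], B = soc_r[2], C = soc_nr[1], D = soc_nr[2])
  dvals <- list(A = den_r[1], B = den_r[2], C = den_nr[1], D = den_nr[2])
  rows <- do.call(rbind, lapply(names(pats), function(p) {
    rbind(data.frame(patient_id = p, roi_id = sprintf("R%d", 1:n_rois),
                     outcome = pats[[p]], metric = "soc",
                     value = rep(vals[[p]], n_rois)),
          data.frame(patient_id = p, roi_id = sprintf("R%d", 1:n_rois),
                     outcome = pats[[p]], metric = "den",
                     value = rep(dvals[[p]], n_rois)))
  }))
  cohort_table(rows$patient_id, rows$roi_id, rows$outcome, rows$metric,
               rows$value)
}

test_that("benefit score: sociology-separated, density-flat cohorts improve all patients", {
  # density identical everywhere (uninformative); sociology separates the
  # groups by far more than the within-group spread
  co <- bench_cohort(soc_r = c(0.10, 0.12), soc_nr = c(0.90, 0.92),
                     den_r = c(5, 5), den_nr = c(5, 5))
  sc <- roi_benefit_score(co, "den", "soc", leave_one_out = FALSE)
  expect_true(all(sc$verdict == "improved"))
  expect_true(all(sc$sociology_delta == 5))
})

test_that("benefit score: adversarial sociology gives -n_rois and misclassification", {
  # patient A (recurrent) sits squarely in the non-recurrent sociology
  # interval for every ROI
  pats <- c(A = "recurrent", B = "recurrent",
            C = "non_recurrent", D = "non_recurrent")
  rows <- do.call(rbind, lapply(names(pats), function(p) {
    soc <- switch(p, A = 0.9, B = 0.1, C = 0.9, D = 0.92)
    rbind(data.frame(patient_id = p, roi_id = sprintf("R%d", 1:5),
                     outcome = pats[[p]], metric = "soc", value = rep(soc, 5)),
          data.frame(patient_id = p, roi_id = sprintf("R%d", 1:5),
                     outcome = pats[[p]], metric = "den", value = rep(1, 5)))
  }))
  co <- cohort_table(rows$patient_id, rows$roi_id, rows$outcome, rows$metric,
                     rows$value)
  sc <- roi_benefit_score(co, "den", "soc", leave_one_out = TRUE)
  a <- sc[sc$patient_id == "A", ]
  expect_equal(a$sociology_delta, -5L)
  expect_equal(a$verdict, "misclassified")
})

test_that("ROIs inside both intervals contribute zero", {
  # sociology overlaps completely across groups -> uninformative -> 0
  co <- bench_cohort(soc_r = c(0.4, 0.6), soc_nr = c(0.4, 0.6),
                     den_r = c(1, 1), den_nr = c(1, 1))
  sc <- roi_benefit_score(co, "den", "soc", leave_one_out = FALSE)
  expect_true(all(sc$sociology_delta == 0))
  expect_true(all(sc$verdict == "no_change"))
})

test_that("scores stay within [-n_rois, n_rois] and swap with outcome labels", {
  set.seed(9)
  pats <- sprintf("P%d", 1:8)
  out <- setNames(rep(c("recurrent", "non_recurrent"), each = 4), pats)
  rows <- do.call(rbind, lapply(pats, function(p) {
    rbind(data.frame(patient_id = p, roi_id = sprintf("R%d", 1:5),
                     outcome = out[[p]], metric = "soc", value = runif(5)),
          data.frame(patient_id = p, roi_id = sprintf("R%d", 1:5),
                     outcome = out[[p]], metric = "den", value = rep(1, 5)))
  }))
  co <- cohort_table(rows$patient_id, rows$roi_id, rows$outcome, rows$metric,
                     rows$value)
  sc <- roi_benefit_score(co, "den", "soc")
  expect_true(all(abs(sc$sociology_delta) <= 5))
  # consistently renaming both outcome groups is a pure relabelling and
  # leaves every score unchanged
  rows_all <- rows
  rows_all$outcome <- ifelse(rows$outcome == "recurrent", "non_recurrent",
                             "recurrent")
  co_all <- cohort_table(rows_all$patient_id, rows_all$roi_id,
                         rows_all$outcome, rows_all$metric, rows_all$value)
  sc_all <- roi_benefit_score(co_all, "den", "soc")
  expect_equal(sc_all$sociology_delta, sc$sociology_delta)
  # flipping ONE patient's recorded outcome (leave-one-out intervals, so
  # that patient's calls are unchanged) exchanges its +1 and -1
  # contributions: density is everywhere uninformative, so each informative
  # sociology call flips between correct (+1) and incorrect (-1)
  for (p in pats[c(1, 5)]) {
    rows_p <- rows
    flip <- rows_p$patient_id == p
    rows_p$outcome[flip] <- ifelse(rows_p$outcome[flip] == "recurrent",
                                   "non_recurrent", "recurrent")
    co_p <- cohort_table(rows_p$patient_id, rows_p$roi_id, rows_p$outcome,
                         rows_p$metric, rows_p$value)
    sc_p <- roi_benefit_score(co_p, "den", "soc", leave_one_out = TRUE)
    expect_equal(sc_p$sociology_delta[sc_p$patient_id == p],
                 -sc$sociology_delta[sc$patient_id == p], label = p)
  }
})

test_that("cohort_table validates outcomes", {
  expect_error(cohort_table("P1", "R1", "x", "m", 1), "two values")
  expect_error(
    cohort_table(c("P1", "P1"), c("R1", "R2"), c("a", "b"), "m", c(1, 2)),
    "one outcome")
})
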