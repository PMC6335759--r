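# Cohort-level comparison of density and sociology metrics between outcome
# groups, and the per-patient ROI-level classification-benefit score.

#' Build a long-format cohort table
#'
#' @param patient_id,roi_id,outcome,metric,value Equal-length vectors; one
#'   row per (patient, ROI, metric). `outcome` must take exactly two values
#'   (e.g. `"recurrent"`, `"non_recurrent"`) and be constant within patient.
#' @return data.frame of class `cohort_table`.
#' @export
cohort_table <- function(patient_id, roi_id, outcome, metric, value) {
  df <- data.frame(patient_id = as.character(patient_id),
                   roi_id = as.character(roi_id),
                   outcome = as.character(outcome),
                   metric = as.character(metric),
                   value = as.numeric(value))
  per_pat <- tapply(df$outcome, df$patient_id, function(o) length(unique(o)))
  if (any(per_pat != 1)) stop("each patient must have exactly one outcome")
  if (length(unique(df$outcome)) != 2) {
    stop("outcome must take exactly two values")
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Compare a metric between the two outcome groups (Mann-Whitney U)
#'
#' Two-sided Wilcoxon rank-sum test on ROI-level values pooled by outcome
#' group: exact distribution for small untied samples, normal approximation
#' with tie correction otherwise (the behaviour of [stats::wilcox.test()]).
#'
#' @param cohort A [cohort_table()].
#' @param metric Metric name to test.
#' @return List with `metric`, `p_value`, `statistic`, and per-group `n`,
#'   `mean`, `sd`.
#' @export
compare_groups <- function(cohort, metric) {
  rows <- cohort[cohort$metric == metric, , drop = FALSE]
  if (nrow(rows) == 0) stop("no rows for metric '", metric, "'")
  groups <- sort(unique(cohort$outcome))
  v1 <- rows$value[rows$outcome == groups[1]]
  v2 <- rows$value[rows$outcome == groups[2]]
  if (length(v1) == 0 || length(v2) == 0) {
    stop("both outcome groups must be non-empty for metric '", metric, "'")
  }
  wt <- suppressWarnings(wilcox.test(v1, v2, alternative = "two.sided"))
  list(metric = metric, p_value = wt$p.value, statistic = unname(wt$statistic),
       groups = groups,
       n = c(length(v1), length(v2)),
       mean = c(mean(v1), mean(v2)),
       sd = c(sd(v1), sd(v2)))
}

# mean +/- sd interval of a group's ROI-level values for one metric,
# optionally excluding one patient (leave-one-patient-out)
group_interval <- function(rows, group, exclude_patient = NULL) {
  sel <- rows$outcome == group
  if (!is.null(exclude_patient)) sel <- sel & rows$patient_id != exclude_patient
  v <- rows$value[sel]
  if (length(v) == 0) return(c(NA_real_, NA_real_))
  s <- if (length(v) > 1) sd(v) else 0
  c(mean(v) - s, mean(v) + s)
}

#' ROI-level classification-benefit score of sociology over density
#'
#' Formalization of the per-patient comparison of a sociology metric against
#' a density metric. For each metric, each outcome group g gets the interval
#' `[mean_g - sd_g, mean_g + sd_g]` of its ROI-level values. An ROI value is
#' *informative* for a metric when it falls inside exactly one group's
#' interval (that group is its call) and uninformative otherwise (inside
#' both or neither). Per ROI: `+1` when density is uninformative and the
#' sociology call matches the patient's true outcome; `-1` when sociology is
#' informative but calls the wrong group; `0` otherwise. ROI scores are
#' summed per patient: positive sums mean sociology improved on density
#' (`improved`), negative sums mean it misled (`misclassified`), zero means
#' `no_change`.
#'
#' By default the group intervals exclude the patient being scored
#' (leave-one-patient-out), so a patient never helps classify itself; set
#' `leave_one_out = FALSE` to pool all patients.
#'
#' @param cohort A [cohort_table()] containing both metrics.
#' @param density_metric,sociology_metric Metric names.
#' @param leave_one_out Exclude the scored patient from the group intervals
#'   (default TRUE).
#' @return data.frame, one row per patient: `patient_id`, `outcome`,
#'   `n_rois`, `density_correct` (any ROI informative-and-correct by
#'   density), `sociology_delta` (the summed score) and `verdict`.
#' @export
roi_benefit_score <- function(cohort, density_metric, sociology_metric,
                              leave_one_out = TRUE) {
  den <- cohort[cohort$metric == density_metric, , drop = FALSE]
  soc <- cohort[cohort$metric == sociology_metric, , drop = FALSE]
  if (nrow(den) == 0) stop("no rows for metric '", density_metric, "'")
  if (nrow(soc) == 0) stop("no rows for metric '", sociology_metric, "'")
  groups <- sort(unique(cohort$outcome))
  patients <- unique(cohort$patient_id)

  call_one <- function(value, i1, i2) {
    in1 <- is.finite(i1[1]) && value >= i1[1] && value <= i1[2]
    in2 <- is.finite(i2[1]) && value >= i2[1] && value <= i2[2]
    if (in1 && !in2) return(groups[1])
    if (in2 && !in1) return(groups[2])
    NA_character_ # uninformative: inside both or neither
  }

  out <- lapply(patients, function(p) {
    excl <- if (leave_one_out) p else NULL
    d1 <- group_interval(den, groups[1], excl)
    d2 <- group_interval(den, groups[2], excl)
    s1 <- group_interval(soc, groups[1], excl)
    s2 <- group_interval(soc, groups[2], excl)
    truth <- cohort$outcome[cohort$patient_id == p][1]
    rois <- unique(den$roi_id[den$patient_id == p])
    delta <- 0L
    dens_correct <- FALSE
    for (r in rois) {
      dv <- den$value[den$patient_id == p & den$roi_id == r][1]
      sv <- soc$value[soc$patient_id == p & soc$roi_id == r][1]
      d_call <- if (is.finite(dv)) call_one(dv, d1, d2) else NA_character_
      s_call <- if (is.finite(sv)) call_one(sv, s1, s2) else NA_character_
      if (!is.na(d_call) && d_call == truth) dens_correct <- TRUE
      if (!is.na(s_call)) {
        if (s_call != truth) {
          delta <- delta - 1L
        } else if (is.na(d_call)) {
          delta <- delta + 1L
        }
      }
    }
    data.frame(patient_id = p, outcome = truth, n_rois = length(rois),
               density_correct = dens_correct, sociology_delta = delta,
               verdict = if (delta > 0) "improved"
                         else if (delta < 0) "misclassified" else "no_change")
  })
  do.call(rbind, out)
}

#' Heatmap of per-patient benefit scores
#'
#' @param scores Output of [roi_benefit_score()] (optionally several cell
#'   types rbound with a `cell_type` column).
#' @param ... Passed to [graphics::image()].
#' @export
plot_benefit_scores <- function(scores, ...) {
  ct <- if (!is.null(scores$cell_type)) scores$cell_type else "score"
  tab <- tapply(scores$sociology_delta, list(ct, scores$patient_id), mean)
  image(seq_len(ncol(tab)), seq_len(nrow(tab)), t(tab),
        col = hcl.colors(21, "Blue-Red 3", rev = TRUE),
        xlab = "patient", ylab = "", axes = FALSE, ...)
  graphics::axis(1, seq_len(ncol(tab)), colnames(tab), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(nrow(tab)), rownames(tab), las = 1, cex.axis = 0.7)
  invisible(tab)
}
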