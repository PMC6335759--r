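#' Fixed-position label-permutation Monte Carlo test of a neighbor frequency
#'
#' Tests whether the observed mean neighbor frequency of one (focal,
#' neighbor) phenotype pair could arise from a random arrangement of the
#' phenotypes over the observed cell positions. Cell positions and the
#' Voronoi graph are held fixed; the phenotype labels of all non-EXCLUDED
#' cells are permuted uniformly at random (sampling without replacement, so
#' each replicate preserves the exact per-phenotype counts), and the mean
#' neighbor frequency is recomputed for each replicate. The z-score is
#' `(observed - mean(replicates)) / sd(replicates)` with the sample (n-1)
#' standard deviation. `|z| > 3` is flagged non-random; highly negative
#' z-scores indicate avoidance, highly positive ones colocalization.
#'
#' EXCLUDED cells keep their label and position in every replicate.
#'
#' @inheritParams neighbor_frequency
#' @param focal,neighbor Phenotype labels of the tested ordered pair.
#' @param n_iter Number of permutation replicates (default 500).
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `null_distribution`: list with `focal`,
#'   `neighbor`, `observed`, `replicates`, `null_mean`, `null_sd`, `z`,
#'   `nonrandom`, `degenerate`, `n_iter`, `seed`.
#' @examples
#' set.seed(1)
#' cells <- data.frame(id = 1:40, x = runif(40, 0, 100), y = runif(40, 0, 100),
#'                     phenotype = sample(c("A", "B"), 40, TRUE))
#' g <- build_graph(cells, rect_roi(0, 0, 100, 100))
#' permutation_test(g, "A", "B", n_iter = 100, seed = 7)
#' @export
permutation_test <- function(graph, focal, neighbor, n_iter = 500,
                             seed = NULL, cells = NULL) {
  labels <- graph_labels(graph, cells)
  if (n_iter < 2) stop("n_iter must be at least 2")
  for (p in unique(c(focal, neighbor))) {
    if (!any(labels == p)) stop("no cells with phenotype '", p, "'")
  }
  de <- directed_edges(graph)
  observed <- mean_pair_frequency(de, labels, focal, neighbor)

  if (!is.null(seed)) set.seed(seed)
  free <- which(labels != EXCLUDED_LABEL)
  replicates <- numeric(n_iter)
  lab_i <- labels
  for (r in seq_len(n_iter)) {
    lab_i[free] <- labels[sample(free)]
    replicates[r] <- mean_pair_frequency(de, lab_i, focal, neighbor)
  }

  null_mean <- mean(replicates)
  null_sd <- sd(replicates)
  degenerate <- !is.finite(null_sd) || null_sd == 0
  z <- if (degenerate) NA_real_ else (observed - null_mean) / null_sd

  structure(
    list(focal = focal, neighbor = neighbor, observed = observed,
         replicates = replicates, null_mean = null_mean, null_sd = null_sd,
         z = z, nonrandom = isTRUE(abs(z) > 3), degenerate = degenerate,
         n_iter = n_iter, seed = seed),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Permutation null for f(%s -> %s): observed %.4f, null %.4f +/- %.4f\n",
              x$focal, x$neighbor, x$observed, x$null_mean, x$null_sd))
  if (x$degenerate) {
    cat("z: degenerate (null sd = 0)\n")
  } else {
    cat(sprintf("z = %.2f (%s; |z| > 3 deemed non-random), %d replicates\n",
                x$z, if (x$nonrandom) "non-random" else "consistent with random",
                x$n_iter))
  }
  invisible(x)
}

#' @export
plot.null_distribution <- function(x, ...) {
  hist(x$replicates, breaks = "FD", col = "grey85", border = "white",
       main = sprintf("Null of f(%s -> %s)", x$focal, x$neighbor),
       xlab = "mean neighbor frequency",
       xlim = range(c(x$replicates, x$observed)))
  abline(v = x$observed, col = "red3", lwd = 2)
  invisible(x)
}

#' Permutation z-scores for all ordered phenotype pairs
#'
#' Runs [permutation_test()] for every ordered pair of (by default) all
#' non-EXCLUDED phenotypes present, reusing one replicate stream per seed.
#'
#' @inheritParams permutation_test
#' @param pairs Either `"all"` or a data.frame with columns `focal`,
#'   `neighbor`.
#' @return A data.frame: `focal`, `neighbor`, `observed`, `null_mean`,
#'   `null_sd`, `z`, `nonrandom`, `n_iter`, `seed`.
#' @export
sociology_zscores <- function(graph, pairs = "all", n_iter = 500,
                              seed = NULL, cells = NULL) {
  labels <- graph_labels(graph, cells)
  if (identical(pairs, "all")) {
    ph <- sort(setdiff(unique(labels), EXCLUDED_LABEL))
    pairs <- expand.grid(neighbor = ph, focal = ph,
                         stringsAsFactors = FALSE)[, 2:1]
  }
  out <- lapply(seq_len(nrow(pairs)), function(k) {
    nd <- permutation_test(graph, pairs$focal[k], pairs$neighbor[k],
                           n_iter = n_iter,
                           seed = if (is.null(seed)) NULL else seed + k,
                           cells = cells)
    data.frame(focal = nd$focal, neighbor = nd$neighbor,
               observed = nd$observed, null_mean = nd$null_mean,
               null_sd = nd$null_sd, z = nd$z, nonrandom = nd$nonrandom,
               n_iter = nd$n_iter,
               seed = if (is.null(nd$seed)) NA_integer_ else nd$seed)
  })
  do.call(rbind, out)
}
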