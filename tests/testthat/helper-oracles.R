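# Independent oracles, deliberately written along different code paths than
# the package implementations they check.

# Brute-force Voronoi adjacency: for each unordered pair (i, j) the shared
# Voronoi boundary is the set of points on the perpendicular bisector that
# are closer to i (and j) than to every other generator, restricted to the
# bounding rectangle. Each "closer than k" half-plane constraint and each
# rectangle side is a 1-D interval in the bisector's arc-length parameter;
# the pair is adjacent iff the intersection of all intervals is longer than
# eps. O(n^2) pairs x O(n) constraints.
oracle_voronoi_edges <- function(x, y, xmin, ymin, xmax, ymax, eps = 1e-9) {
  n <- length(x)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      mx <- (x[i] + x[j]) / 2
      my <- (y[i] + y[j]) / 2
      dx <- x[j] - x[i]; dy <- y[j] - y[i]
      dn <- sqrt(dx^2 + dy^2)
      ux <- -dy / dn; uy <- dx / dn # unit direction along the bisector
      lo <- -Inf; hi <- Inf
      clip <- function(a, b, lo, hi) {
        # constraint a*t + b <= 0
        if (abs(a) < 1e-300) {
          if (b > 0) return(c(1, 0)) # infeasible
          return(c(lo, hi))
        }
        t0 <- -b / a
        if (a > 0) c(lo, min(hi, t0)) else c(max(lo, t0), hi)
      }
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        a <- 2 * (ux * (x[k] - x[i]) + uy * (y[k] - y[i]))
        b <- 2 * (mx * (x[k] - x[i]) + my * (y[k] - y[i])) +
          x[i]^2 + y[i]^2 - x[k]^2 - y[k]^2
        r <- clip(a, b, lo, hi); lo <- r[1]; hi <- r[2]
        if (hi - lo <= eps) break
      }
      if (hi - lo > eps) {
        # rectangle constraints: xmin <= mx + t*ux <= xmax, same for y
        r <- clip(-ux, xmin - mx, lo, hi); lo <- r[1]; hi <- r[2]
        r <- clip(ux, mx - xmax, lo, hi); lo <- r[1]; hi <- r[2]
        r <- clip(-uy, ymin - my, lo, hi); lo <- r[1]; hi <- r[2]
        r <- clip(uy, my - ymax, lo, hi); lo <- r[1]; hi <- r[2]
      }
      if (hi - lo > eps) out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (length(out) == 0) return(matrix(integer(0), ncol = 2))
  do.call(rbind, out)
}

# Brute-force non-negative least squares by support enumeration: solve the
# unconstrained LS problem on every subset of the variables, keep feasible
# solutions, return the best.
oracle_nnls <- function(A, b) {
  k <- ncol(A)
  best <- rep(0, k)
  best_r <- sum(b^2)
  for (mask in 1:(2^k - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    As <- A[, idx, drop = FALSE]
    xs <- tryCatch(solve(crossprod(As), crossprod(As, b)),
                   error = function(e) NULL)
    if (is.null(xs) || any(xs < 0)) next
    r <- sum((b - As %*% xs)^2)
    if (r < best_r - 1e-12) {
      best_r <- r
      best <- rep(0, k)
      best[idx] <- xs
    }
  }
  best
}

# Exact two-sided rank-sum p-value by enumerating every assignment of the
# pooled values to the two groups (no ties assumed).
oracle_ranksum_p <- function(v1, v2) {
  n1 <- length(v1)
  pooled <- c(v1, v2)
  rk <- rank(pooled)
  w_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  ws <- apply(combos, 2, function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# Plain-loop neighbor-frequency summary from an explicit adjacency list;
# used to hand-check summarize_sociology on small fixtures.
oracle_mean_frequency <- function(adj_ids, labels, ids, focal, neighbor) {
  vals <- c()
  for (i in seq_along(ids)) {
    if (labels[i] != focal) next
    nb <- match(adj_ids[[i]], ids)
    nl <- labels[nb]
    nl <- nl[nl != "EXCLUDED"]
    if (length(nl) == 0) next
    vals <- c(vals, sum(nl == neighbor) / length(nl))
  }
  if (length(vals) == 0) return(NA_real_)
  mean(vals)
}
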