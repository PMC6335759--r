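# Fixture builders shared across test files. All fixtures are generated in
# code; none are read from disk.

# Focal cell at the center of a ring of neighbors: the center's Voronoi
# cell is enclosed by the ring, so its neighbors are exactly the ring cells.
ring_fixture <- function(neighbor_labels, focal_label = "focal",
                         radius = 20, center = c(50, 50)) {
  k <- length(neighbor_labels)
  ang <- 2 * pi * (seq_len(k) - 1) / k
  cells <- data.frame(
    id = seq_len(k + 1),
    x = c(center[1], center[1] + radius * cos(ang)),
    y = c(center[2], center[2] + radius * sin(ang)),
    phenotype = c(focal_label, neighbor_labels)
  )
  list(cells = cells,
       roi = rect_roi(0, 0, 2 * center[1], 2 * center[2]))
}

# Sum-of-Gaussians intensity map (independent of render_cube).
blob_map <- function(cx, cy, sigma, amp, nr, nc) {
  m <- matrix(0, nr, nc)
  ys <- 0:(nr - 1); xs <- 0:(nc - 1)
  for (k in seq_along(cx)) {
    g <- outer(exp(-(ys - cy[k])^2 / (2 * sigma[k]^2)),
               exp(-(xs - cx[k])^2 / (2 * sigma[k]^2)))
    m <- m + amp[k] * g
  }
  m
}

# 30 well-separated Gaussian nuclei on a 6 x 5 grid; every blob's
# above-threshold footprint is in the 120-400 px range.
thirty_blob_fixture <- function() {
  gx <- rep(seq(25, 275, by = 50), times = 5)
  gy <- rep(seq(25, 225, by = 50), each = 6)
  set.seed(30)
  sig <- runif(30, 4, 5.5)
  map <- blob_map(gx, gy, sig, rep(1, 30), 250, 300)
  list(map = map, x = gx, y = gy)
}

# Two equal disks of ~300 px overlapping by about 10% of their area.
touching_disks_fixture <- function(r = 9.77, sep = 16) {
  nr <- 60; nc <- 80
  ys <- 0:(nr - 1); xs <- 0:(nc - 1)
  c1 <- c(32, 30); c2 <- c(32 + sep, 30)
  d1 <- outer((ys - c1[2])^2, (xs - c1[1])^2, "+") < r^2
  d2 <- outer((ys - c2[2])^2, (xs - c2[1])^2, "+") < r^2
  (d1 | d2) * 1.0
}

uniform_label_cells <- function(n, side, labels, prob, seed) {
  set.seed(seed)
  data.frame(id = seq_len(n), x = runif(n, 0, side), y = runif(n, 0, side),
             phenotype = sample(labels, n, replace = TRUE, prob = prob))
}
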