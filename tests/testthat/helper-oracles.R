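# Independent oracles and small fixture builders used across the suite.

# Exhaustive optimal 1-D k-means by enumerating contiguous partitions of the
# sorted distinct values (optimal 1-D clusterings are contiguous). Returns
# the minimal weighted within-cluster sum of squares.
enumerate_kmeans_inertia <- function(values, weights, k) {
  ord <- order(values)
  v <- values[ord]; w <- weights[ord]
  d <- length(v)
  stopifnot(k <= d)
  seg_cost <- function(i, j) {
    vv <- v[i:j]; ww <- w[i:j]
    sum(ww * vv^2) - sum(ww * vv)^2 / sum(ww)
  }
  if (k == 1) return(seg_cost(1, d))
  best <- Inf
  for (cuts in utils::combn(d - 1, k - 1, simplify = FALSE)) {
    bounds <- c(0, cuts, d)
    cost <- 0
    for (s in seq_len(k)) cost <- cost + seg_cost(bounds[s] + 1, bounds[s + 1])
    best <- min(best, cost)
  }
  best
}

# Point-in-polygon convex hull oracle: a pixel belongs to the hull iff its
# center lies inside or on the convex polygon of the foreground pixel
# centers. Written independently of the package's scanline fill (signed
# cross-product test per edge; degenerate cases via distance to segment).
hull_oracle <- function(mask) {
  idx <- which(mask == 1L, arr.ind = TRUE)
  r <- idx[, 1]; c <- idx[, 2]
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (nrow(idx) == 0L) stop("empty mask")
  h <- grDevices::chull(c, r)
  px <- c[h]; py <- r[h]
  nv <- length(px)
  tol <- 1e-9
  if (nv <= 2L || abs(sum(px * py[c(nv, seq_len(nv - 1))] -
                          px[c(nv, seq_len(nv - 1))] * py)) / 2 < tol) {
    # collinear: pixels whose center lies on the extreme segment
    d2 <- (r - r[1])^2 + (c - c[1])^2
    a <- which.max(d2)
    b <- which.max((r - r[a])^2 + (c - c[a])^2)
    for (rr in seq_len(nrow(mask))) for (cc in seq_len(ncol(mask))) {
      d <- dist_point_segment(rr, cc, r[a], c[a], r[b], c[b])
      if (d < tol) out[rr, cc] <- 1L
    }
    return(out)
  }
  # consistent orientation via signed area; a point is inside iff every
  # edge cross product has the polygon's orientation sign (or is ~0)
  sgn <- sign(sum(px * py[c(2:nv, 1)] - px[c(2:nv, 1)] * py))
  for (rr in seq_len(nrow(mask))) for (cc in seq_len(ncol(mask))) {
    inside <- TRUE
    for (e in seq_len(nv)) {
      x1 <- px[e]; y1 <- py[e]
      x2 <- px[e %% nv + 1L]; y2 <- py[e %% nv + 1L]
      cr <- (x2 - x1) * (rr - y1) - (y2 - y1) * (cc - x1)
      if (sgn * cr < -tol) { inside <- FALSE; break }
    }
    if (inside) out[rr, cc] <- 1L
  }
  out
}

dist_point_segment <- function(pr, pc, r1, c1, r2, c2) {
  dr <- r2 - r1; dc <- c2 - c1
  len2 <- dr^2 + dc^2
  if (len2 == 0) return(sqrt((pr - r1)^2 + (pc - c1)^2))
  t <- max(0, min(1, ((pr - r1) * dr + (pc - c1) * dc) / len2))
  sqrt((pr - r1 - t * dr)^2 + (pc - c1 - t * dc)^2)
}

# Random small blob-ish binary mask (union of random rectangles and points).
random_mask <- function(nr, nc, density = 0.5) {
  m <- matrix(0L, nr, nc)
  n_rect <- sample(1:3, 1)
  for (i in seq_len(n_rect)) {
    r0 <- sample(nr, 1); c0 <- sample(nc, 1)
    r1 <- min(nr, r0 + sample(0:5, 1)); c1 <- min(nc, c0 + sample(0:5, 1))
    m[r0:r1, c0:c1] <- 1L
  }
  extra <- which(matrix(runif(nr * nc), nr, nc) < density * 0.05)
  m[extra] <- 1L
  m
}

# Random histogram with at most `max_distinct` occupied bins.
random_histogram <- function(max_distinct = 12, max_count = 30) {
  counts <- integer(256)
  d <- sample(2:max_distinct, 1)
  bins <- sample(0:255, d)
  counts[bins + 1] <- sample.int(max_count, d, replace = TRUE)
  structure(counts, class = "heartseg_histogram")
}

# Small phantom used by several tests: 96 x 96, 3 slices, liver from slice 3.
small_phantom <- function(seed = 1, n_slices = 3L, shape = 96L,
                          liver_onset = 3L) {
  generate_phantom(phantom_spec(n_slices = n_slices, shape = shape,
                                liver_onset_slice = liver_onset, seed = seed))
}
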