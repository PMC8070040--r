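#' Intensity histogram of a grayscale image or stack
#'
#' Collapses grayscale pixels (integers in 0..255) into a 256-bin count
#' vector. Because intensities are discrete, clustering and silhouette
#' scoring on the histogram are mathematically identical to operating on the
#' raw pixel vector, at a fraction of the cost.
#'
#' @param x Integer vector, matrix or array of grayscale values in 0..255.
#' @return Integer vector of length 256 (`counts[v + 1]` is the number of
#'   pixels with value `v`), class `"heartseg_histogram"`.
#' @export
#' @examples
#' h <- intensity_histogram(c(0L, 0L, 255L))
#' h[c(1, 256)]
intensity_histogram <- function(x) {
  v <- as.integer(x)
  if (anyNA(v)) stop("grayscale values must not contain NA", call. = FALSE)
  if (any(v < 0L | v > 255L)) {
    stop("grayscale values must lie in [0, 255]", call. = FALSE)
  }
  counts <- tabulate(v + 1L, nbins = 256L)
  structure(counts, class = "heartseg_histogram")
}

hist_as_counts <- function(hist) {
  if (inherits(hist, "heartseg_histogram")) return(as.integer(unclass(hist)))
  h <- as.integer(hist)
  if (length(h) != 256L || any(h < 0L)) {
    stop("histogram must be a 256-vector of non-negative counts", call. = FALSE)
  }
  h
}

#' 1-D K-Means over an intensity histogram
#'
#' Histogram-weighted Lloyd's algorithm with k-means++ initialization and
#' multiple restarts, minimizing the within-cluster sum of squared distances
#' of pixels to their nearest centroid. Operating on the 256-bin histogram is
#' exactly equivalent to clustering the expanded pixel multiset and makes a
#' full 512x512 slice clusterable in O(256 k) per iteration. Because the
#' optimal 1-D clustering is contiguous in the sorted values, the restart
#' winner is additionally checked against the exact dynamic-programming
#' optimum, so the returned inertia is the global minimum of the objective.
#'
#' @param hist 256-bin histogram from [intensity_histogram()].
#' @param k Number of clusters (1..number of distinct occupied bins).
#' @param seed Integer seed controlling the k-means++ draws; restarts use
#'   `seed`, `seed + 1`, ... so runs are reproducible.
#' @param n_init Number of independent restarts; the solution with the lowest
#'   inertia wins.
#' @param tol Convergence threshold on the maximum centroid movement.
#' @param max_iter Iteration cap per restart.
#' @return An object of class `"heartseg_centroids"`: a list with `k`,
#'   `values` (ascending centroids), `inertia`, and `seed`.
#' @export
#' @examples
#' h <- intensity_histogram(c(0L, 0L, 0L, 10L, 10L, 10L))
#' kmeans_1d(h, k = 2)$values
kmeans_1d <- function(hist, k, seed = 0L, n_init = 10L, tol = 1e-4,
                      max_iter = 300L) {
  counts <- hist_as_counts(hist)
  if (sum(counts) == 0L) stop("histogram is empty", call. = FALSE)
  vals <- which(counts > 0L) - 1L      # occupied intensity values
  w <- as.numeric(counts[vals + 1L])
  d <- length(vals)
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  if (k > d) {
    stop(sprintf("k = %d exceeds the %d distinct intensity values", k, d),
         call. = FALSE)
  }
  if (k == d) {  # every occupied bin its own cluster: exact, inertia 0
    return(new_centroids(k, as.numeric(vals), 0, seed))
  }

  v <- as.numeric(vals)
  best <- NULL
  with_local_seed(seed, {
    for (init in seq_len(n_init)) {
      centers <- kpp_init(v, w, k)
      fit <- lloyd_1d(v, w, centers, tol, max_iter)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  # Restarted Lloyd can still land in a local minimum. In 1-D the global
  # optimum is contiguous in the sorted values and computable exactly by
  # dynamic programming, so polish the restart winner with the DP solution.
  dp <- dp_optimal_1d(v, w, k)
  if (dp$inertia < best$inertia - 1e-12) best <- dp
  new_centroids(k, sort(best$centers), best$inertia, seed)
}

# Exact weighted 1-D k-means via dynamic programming over contiguous
# partitions of the sorted values; O(k d^2) for d distinct values.
dp_optimal_1d <- function(v, w, k) {
  d <- length(v)
  cw <- cumsum(w); cwv <- cumsum(w * v); cwv2 <- cumsum(w * v^2)
  seg <- function(i, j) {
    sw <- cw[j] - if (i > 1) cw[i - 1] else 0
    sv <- cwv[j] - if (i > 1) cwv[i - 1] else 0
    sv2 <- cwv2[j] - if (i > 1) cwv2[i - 1] else 0
    sv2 - sv^2 / sw
  }
  cost <- matrix(Inf, k, d)     # cost[m, j]: first j values in m clusters
  back <- matrix(0L, k, d)
  for (j in 1:d) cost[1, j] <- seg(1, j)
  if (k > 1) {
    for (m in 2:k) {
      for (j in m:d) {
        for (i in m:j) {
          val <- cost[m - 1, i - 1] + seg(i, j)
          if (val < cost[m, j]) { cost[m, j] <- val; back[m, j] <- i }
        }
      }
    }
  }
  # recover segment means
  centers <- numeric(k)
  j <- d
  for (m in k:1) {
    i <- if (m == 1) 1L else back[m, j]
    sw <- cw[j] - if (i > 1) cw[i - 1] else 0
    sv <- cwv[j] - if (i > 1) cwv[i - 1] else 0
    centers[m] <- sv / sw
    j <- i - 1L
  }
  list(centers = centers, inertia = cost[k, d])
}

new_centroids <- function(k, values, inertia, seed) {
  structure(
    list(k = as.integer(k), values = as.numeric(values),
         inertia = as.numeric(inertia), seed = as.integer(seed)),
    class = "heartseg_centroids"
  )
}

#' @export
print.heartseg_centroids <- function(x, ...) {
  cat(sprintf("1-D K-Means centroids (k = %d, inertia = %.4g)\n", x$k, x$inertia))
  cat("  ", paste(formatC(x$values, digits = 4, format = "fg"), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# k-means++ seeding on weighted points.
kpp_init <- function(v, w, k) {
  centers <- numeric(k)
  centers[1] <- v[sample.int(length(v), 1L, prob = w)]
  if (k > 1L) {
    d2 <- (v - centers[1])^2
    for (j in 2:k) {
      p <- w * d2
      if (sum(p) <= 0) {  # all mass already on chosen centers
        centers[j] <- v[sample.int(length(v), 1L, prob = w)]
      } else {
        centers[j] <- v[sample.int(length(v), 1L, prob = p)]
      }
      d2 <- pmin(d2, (v - centers[j])^2)
    }
  }
  centers
}

# Weighted Lloyd iterations; empty clusters are re-seeded at the occupied
# value farthest from its current centroid.
lloyd_1d <- function(v, w, centers, tol, max_iter) {
  k <- length(centers)
  for (it in seq_len(max_iter)) {
    centers <- sort(centers)
    assign <- nearest_center(v, centers)
    # re-seed empties
    for (j in seq_len(k)) {
      if (!any(assign == j)) {
        dist_own <- abs(v - centers[assign])
        far <- which.max(dist_own)
        centers[j] <- v[far]
        assign <- nearest_center(v, sort(centers))
        centers <- sort(centers)
      }
    }
    new_centers <- vapply(seq_len(k), function(j) {
      sel <- assign == j
      sum(w[sel] * v[sel]) / sum(w[sel])
    }, numeric(1))
    move <- max(abs(new_centers - centers))
    centers <- new_centers
    if (move < tol) break
  }
  centers <- sort(centers)
  assign <- nearest_center(v, centers)
  inertia <- sum(w * (v - centers[assign])^2)
  list(centers = centers, inertia = inertia)
}

# Index of the nearest centroid for each value; ties go to the lower centroid.
nearest_center <- function(v, centers) {
  d <- abs(outer(v, centers, "-"))
  max.col(-d, ties.method = "first")
}

#' Foreground threshold from K-Means centroids
#'
#' The body/air threshold is the arithmetic mean of the centroids, the
#' mean-thresholding criterion used for foreground extraction.
#'
#' @param centroids A `"heartseg_centroids"` object (or numeric vector).
#' @return A single numeric threshold.
#' @export
#' @examples
#' foreground_threshold(c(30, 200))
foreground_threshold <- function(centroids) {
  v <- centroid_values(centroids)
  mean(v)
}

#' Spine threshold from K-Means centroids
#'
#' The spine (bone) threshold is the maximum centroid: with k = 3 clusters
#' over the mediastinal region (injected background, soft tissue, bone), bone
#' occupies the brightest cluster.
#'
#' @inheritParams foreground_threshold
#' @return A single numeric threshold.
#' @export
#' @examples
#' spine_threshold(c(10, 90, 220))
spine_threshold <- function(centroids) {
  v <- centroid_values(centroids)
  max(v)
}

centroid_values <- function(centroids) {
  v <- if (inherits(centroids, "heartseg_centroids")) centroids$values
       else as.numeric(centroids)
  if (length(v) < 1L) stop("at least one centroid required", call. = FALSE)
  v
}

#' Exact silhouette score of a 1-D clustering
#'
#' Mean silhouette `(b - a) / max(a, b)` over all pixels, where `a` is the
#' mean distance of a pixel to the other members of its own cluster and `b`
#' the mean distance to the members of the nearest other cluster. Pixels are
#' assigned to the nearest centroid. Because intensities live on 256 discrete
#' levels, the score is computed exactly from the histogram in O(256^2)
#' bin-pair operations; no sampling is involved. Pixels in single-member
#' clusters score 0 by convention.
#'
#' @param hist 256-bin histogram from [intensity_histogram()].
#' @param centroids `"heartseg_centroids"` (k >= 2) or numeric vector.
#' @return An object of class `"heartseg_silhouette"`: list with
#'   `mean_score` in \[-1, 1\] and `per_cluster_means`.
#' @export
#' @examples
#' h <- intensity_histogram(c(0L, 0L, 10L, 10L))
#' silhouette_1d(h, c(0, 10))$mean_score  # 1: zero-variance, well separated
silhouette_1d <- function(hist, centroids) {
  counts <- hist_as_counts(hist)
  cv <- centroid_values(centroids)
  k <- length(cv)
  if (k < 2L) stop("silhouette requires k >= 2 clusters", call. = FALSE)
  vals <- which(counts > 0L) - 1L
  w <- as.numeric(counts[vals + 1L])
  if (length(vals) == 0L) stop("histogram is empty", call. = FALSE)
  lab <- nearest_center(as.numeric(vals), sort(cv))
  if (length(unique(lab)) < k) {
    stop("degenerate clustering: at least one cluster is empty", call. = FALSE)
  }
  sil_from_bins(as.numeric(vals), w, lab, k)
}

# Shared exact computation over (value, weight, label) bins.
sil_from_bins <- function(v, w, lab, k) {
  n_cl <- vapply(seq_len(k), function(j) sum(w[lab == j]), numeric(1))
  # sumd[i, j] = total distance from bin i to all pixels of cluster j
  dmat <- abs(outer(v, v, "-"))
  sumd <- sapply(seq_len(k), function(j) as.vector(dmat %*% (w * (lab == j))))
  if (is.null(dim(sumd))) sumd <- matrix(sumd, ncol = k)
  s <- numeric(length(v))
  for (i in seq_along(v)) {
    g <- lab[i]
    if (n_cl[g] <= 1) { s[i] <- 0; next }  # singleton-cluster convention
    a <- sumd[i, g] / (n_cl[g] - 1)        # exclude the pixel itself (d = 0)
    b <- min(sumd[i, -g, drop = FALSE] / n_cl[-g])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  per_cluster <- vapply(seq_len(k), function(j) {
    sel <- lab == j
    sum(w[sel] * s[sel]) / sum(w[sel])
  }, numeric(1))
  structure(
    list(mean_score = sum(w * s) / sum(w), per_cluster_means = per_cluster),
    class = "heartseg_silhouette"
  )
}

#' @export
print.heartseg_silhouette <- function(x, ...) {
  cat(sprintf("Mean silhouette score: %.4f\n", x$mean_score))
  invisible(x)
}

#' Brute-force silhouette oracle
#'
#' Literal O(n^2) evaluation of the silhouette definition over an explicit
#' vector of values and cluster labels. Intended as an independent
#' cross-check for [silhouette_1d()] on small inputs.
#'
#' @param values Numeric vector (n <= 5000).
#' @param labels Integer cluster labels, at least two distinct.
#' @return Mean silhouette score.
#' @export
#' @examples
#' silhouette_bruteforce(c(0, 0, 10, 10), c(1, 1, 2, 2))
silhouette_bruteforce <- function(values, labels) {
  n <- length(values)
  if (n > 5000L) stop("oracle limited to n <= 5000", call. = FALSE)
  if (length(labels) != n) stop("values/labels length mismatch", call. = FALSE)
  ulab <- sort(unique(labels))
  if (length(ulab) < 2L) stop("silhouette requires >= 2 clusters", call. = FALSE)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    n_own <- sum(own)
    if (n_own <= 1L) { s[i] <- 0; next }
    a <- sum(abs(values[i] - values[own])) / (n_own - 1)
    b <- min(vapply(ulab[ulab != labels[i]], function(g) {
      mean(abs(values[i] - values[labels == g]))
    }, numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}
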