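test_that("k-means recovers point masses and known small optima", {
  # two point masses: centroids at the masses, zero inertia
  h <- intensity_histogram(c(0L, 0L, 0L, 10L, 10L, 10L))
  fit <- kmeans_1d(h, k = 2)
  expect_equal(fit$values, c(0, 10))
  expect_equal(fit$inertia, 0)

  # {0, 2, 10}, k = 2: partition {0,2}|{10} (inertia 2) beats {0}|{2,10}
  h2 <- intensity_histogram(c(0L, 2L, 10L))
  fit2 <- kmeans_1d(h2, k = 2)
  expect_equal(fit2$values, c(1, 10))
  expect_equal(fit2$inertia, 2)

  # k = 1: the single centroid is the weighted mean
  h3 <- intensity_histogram(c(3L, 5L, 13L))
  fit3 <- kmeans_1d(h3, k = 1)
  expect_equal(fit3$values, 7)

  # k exceeding the number of distinct values is degenerate
  expect_error(kmeans_1d(h, k = 3), "distinct")
})

test_that("k-means result is order-free and deterministic given a seed", {
  px <- sample(rep(c(5L, 40L, 200L), times = c(30, 50, 20)))
  h_a <- intensity_histogram(px)
  h_b <- intensity_histogram(rev(px))
  expect_identical(kmeans_1d(h_a, 2, seed = 3), kmeans_1d(h_b, 2, seed = 3))
})

test_that("histogram Lloyd's matches exhaustive contiguous enumeration", {
  set.seed(42)
  for (case in 1:30) {
    h <- random_histogram(max_distinct = 12)
    counts <- as.integer(unclass(h))
    vals <- which(counts > 0) - 1
    w <- counts[vals + 1]
    for (k in 2:3) {
      if (length(vals) < k) next
      fit <- kmeans_1d(h, k, seed = case)
      opt <- enumerate_kmeans_inertia(vals, w, k)
      expect_lte(fit$inertia, opt + 1e-8)
      expect_gte(fit$inertia, opt - 1e-8)
    }
  }
})

test_that("threshold criteria are the centroid mean and maximum", {
  expect_equal(foreground_threshold(c(0, 10)), 5)
  expect_equal(foreground_threshold(c(30, 200)), 115)
  expect_equal(foreground_threshold(c(0, 100, 200)), 100)
  expect_equal(spine_threshold(c(10, 90, 220)), 220)
  expect_equal(spine_threshold(5), 5)
  # both thresholds lie within the centroid range
  set.seed(7)
  for (i in 1:20) {
    cv <- sort(runif(sample(2:4, 1), 0, 255))
    expect_gte(foreground_threshold(cv), min(cv))
    expect_lte(foreground_threshold(cv), max(cv))
    expect_gte(spine_threshold(cv), min(cv))
    expect_lte(spine_threshold(cv), max(cv))
  }
})

test_that("silhouette of two zero-variance separated clusters is exactly 1", {
  h <- intensity_histogram(c(0L, 0L, 10L, 10L))
  expect_identical(silhouette_1d(h, c(0, 10))$mean_score, 1)
  expect_identical(silhouette_bruteforce(c(0, 0, 10, 10), c(1, 1, 2, 2)), 1)
})

test_that("silhouette matches the hand-verified four-pixel case", {
  # {0,1,9,10} with centroids {0.5, 9.5}: endpoints score 8.5/9.5, inner
  # points 7.5/8.5; mean computed with the brute-force definition
  expected <- mean(c(8.5 / 9.5, 7.5 / 8.5, 7.5 / 8.5, 8.5 / 9.5))
  h <- intensity_histogram(c(0L, 1L, 9L, 10L))
  expect_equal(silhouette_1d(h, c(0.5, 9.5))$mean_score, expected,
               tolerance = 1e-12)
  expect_equal(silhouette_bruteforce(c(0, 1, 9, 10), c(1, 1, 2, 2)),
               expected, tolerance = 1e-12)
})

test_that("single-member clusters score zero by convention", {
  # two singleton clusters: every point is a singleton, so the mean is 0
  h <- intensity_histogram(c(0L, 10L))
  expect_identical(silhouette_1d(h, c(0, 10))$mean_score, 0)
  expect_identical(silhouette_bruteforce(c(0, 10), c(1, 2)), 0)
})

test_that("histogram-exact silhouette equals the brute-force oracle", {
  set.seed(11)
  for (case in 1:50) {
    h <- random_histogram(max_distinct = 10, max_count = 8)
    counts <- as.integer(unclass(h))
    vals <- which(counts > 0) - 1
    k <- if (length(vals) >= 3) sample(2:3, 1) else 2L
    fit <- kmeans_1d(h, k, seed = case)
    exact <- silhouette_1d(h, fit)
    # expand to the pixel multiset and assign to nearest centroid
    px <- rep(vals, counts[vals + 1])
    lab <- vapply(px, function(v) which.min(abs(v - fit$values)), integer(1))
    expect_equal(exact$mean_score, silhouette_bruteforce(px, lab),
                 tolerance = 1e-9)
    expect_gte(exact$mean_score, -1)
    expect_lte(exact$mean_score, 1)
  }
})

test_that("silhouette rejects degenerate clusterings", {
  h <- intensity_histogram(c(0L, 5L, 10L))
  expect_error(silhouette_1d(h, 5), "k >= 2")
  # a centroid that attracts no pixel leaves an empty cluster
  expect_error(silhouette_1d(h, c(0, 10, 200)), "empty")
  expect_error(silhouette_bruteforce(c(1, 2, 3), c(1, 1, 1)), ">= 2")
})
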