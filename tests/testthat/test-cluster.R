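test_that("k-means matches the exhaustive-partition optimum on small instances", {
  X <- make_blobs(4, rbind(c(0, 0), c(6, 5)), sd = 0.8, seed = 1)  # n = 8
  km <- kmeans_lloyd(X, 2, n_init = 10, seed = 3)
  expect_equal(km$wcss, oracle_kmeans_wcss(X, 2), tolerance = 1e-9)
  expect_true(all(km$labels[1:4] == km$labels[1]))
  X3 <- make_blobs(2, rbind(c(0, 0), c(7, 0), c(0, 7)), sd = 0.5, seed = 2)
  km3 <- kmeans_lloyd(X3, 3, n_init = 10, seed = 4)
  expect_equal(km3$wcss, oracle_kmeans_wcss(X3, 3), tolerance = 1e-9)
})

test_that("k-means invariants hold: nearest centroids, member means, WCSS", {
  withr::with_seed(8, X <- matrix(rnorm(40), 20))
  km <- kmeans_lloyd(X, 3, seed = 5)
  d <- as.matrix(dist(rbind(X, km$centers)))[1:20, 21:23]
  expect_equal(km$labels, unname(apply(d, 1, which.min)))
  for (j in 1:3) {
    expect_equal(km$centers[j, ], colMeans(X[km$labels == j, , drop = FALSE]),
      tolerance = 1e-12)
  }
  expect_equal(km$wcss, sum((X - km$centers[km$labels, ])^2), tolerance = 1e-12)
  expect_true(all(diff(km$wcss_trace) <= 1e-9))
  expect_equal(kmeans_lloyd(X, 20, seed = 1)$wcss, 0, tolerance = 1e-12)
  expect_error(kmeans_lloyd(X, 21), "exceeds")
})

test_that("k-means agrees with an independent implementation on separated blobs", {
  X <- make_blobs(10, rbind(c(0, 0), c(8, 0), c(4, 7)), sd = 0.6, seed = 3)
  km <- kmeans_lloyd(X, 3, n_init = 10, seed = 1)
  ref <- stats::kmeans(X, 3, nstart = 10)
  expect_equal(km$wcss, ref$tot.withinss, tolerance = 1e-6)
})

test_that("elbow curves are non-increasing with an advisory knee at the truth", {
  X <- make_blobs(6, rbind(c(0, 0), c(10, 0), c(5, 9)), sd = 0.5, seed = 4)
  ec <- elbow_curve(X, k_range = 1:6, n_init = 5, seed = 2)
  expect_true(all(diff(ec$wcss) <= 1e-9))
  expect_equal(attr(ec, "knee"), 3)
  one <- elbow_curve(X, k_range = 1, n_init = 2, seed = 1)
  expect_equal(one$wcss, sum(sweep(X, 2, colMeans(X))^2), tolerance = 1e-9)
  knees <- vapply(1:50, function(s) {
    Xs <- make_blobs(6, rbind(c(0, 0), c(10, 0), c(5, 9)), sd = 0.6, seed = s)
    attr(elbow_curve(Xs, k_range = 1:6, n_init = 5, seed = s), "knee")
  }, integer(1))
  expect_gte(mean(knees == 3), 0.9)
})

test_that("validity indices match the double-loop oracle to 1e-12", {
  withr::with_seed(6, X <- matrix(rnorm(12), 6))
  labels <- c(1, 1, 1, 2, 2, 2)
  got <- internal_indices(X, labels)
  want <- oracle_indices(X, labels)
  expect_equal(got$silhouette, want$silhouette, tolerance = 1e-12)
  expect_equal(got$davies_bouldin, want$davies_bouldin, tolerance = 1e-12)
  expect_equal(got$calinski_harabasz, want$calinski_harabasz, tolerance = 1e-12)
})

test_that("silhouette agrees with the cluster package and handles singletons", {
  skip_if_not_installed("cluster")
  withr::with_seed(7, X <- matrix(rnorm(24), 12))
  labels <- rep(1:3, each = 4)
  got <- internal_indices(X, labels)$silhouette
  ref <- mean(cluster::silhouette(labels, dist(X))[, 3])
  expect_equal(got, ref, tolerance = 1e-9)
  # singleton clusters score zero by convention
  lab_s <- c(1, 2, rep(3, 10))
  s <- internal_indices(X, lab_s)$silhouette
  expect_true(is.finite(s))
  one_each <- internal_indices(rbind(c(0, 0), c(100, 100)), c(1, 2))
  expect_equal(one_each$silhouette, 0)
})

test_that("indices reach their separation limits on tight far-apart blobs", {
  X <- make_blobs(5, rbind(c(0, 0), c(100, 0)), sd = 0.5, seed = 8)
  idx <- internal_indices(X, rep(1:2, each = 5))
  expect_gt(idx$silhouette, 0.95)
  expect_lt(idx$davies_bouldin, 0.05)
  expect_gt(idx$calinski_harabasz, 1000)
  expect_error(internal_indices(X, rep(1, 10)), "single cluster")
})

test_that("DBSCAN matches the reachability-closure oracle", {
  withr::with_seed(9, X <- matrix(runif(24, 0, 4), 12))
  for (eps in c(0.4, 0.687, 1.2)) {
    expect_equal(dbscan_cluster(X, eps = eps, min_samples = 2),
      oracle_dbscan(X, eps, 2), info = paste("eps", eps))
  }
  # all mutually close: one cluster, no noise
  Xc <- matrix(rnorm(20, sd = 0.05), 10)
  expect_equal(unique(dbscan_cluster(Xc, eps = 1, min_samples = 2)), 1L)
  # an isolated point becomes noise
  Xi <- rbind(matrix(rnorm(10, sd = 0.1), 5), c(50, 50))
  expect_equal(dbscan_cluster(Xi, eps = 1, min_samples = 2)[6], -1L)
})

test_that("cluster descriptives follow the two-point closed form and partition", {
  X <- rbind(c(0, 2), c(4, 6), c(10, 10))
  cd <- cluster_descriptives(X, c(1, 1, 2))
  two <- cd[cd$cluster == 1, ]
  expect_equal(two$mean, c(2, 4))
  expect_equal(two$variance, c((0 - 4)^2 / 2, (2 - 6)^2 / 2))
  expect_equal(two$sd, sqrt(two$variance))
  expect_equal(sum(unique(cd[, c("cluster", "size")])$size), 3)
  singleton <- cd[cd$cluster == 2, ]
  expect_equal(singleton$variance, c(0, 0))
  expect_equal(singleton$size, c(1, 1))
})

test_that("out-of-bag bootstrap CIs are deterministic and bracket strong structure", {
  X <- make_blobs(10, rbind(c(0, 0), c(12, 0)), sd = 0.6, seed = 10)
  r1 <- bootstrap_indices(X, 2, B = 100, seed = 5, n_init = 4)
  r2 <- bootstrap_indices(X, 2, B = 100, seed = 5, n_init = 4)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  sil <- r1[r1$index == "silhouette", ]
  expect_gt(sil$ci_lower, 0.7)
  expect_true(sil$ci_lower <= sil$value && sil$value <= sil$ci_upper)
  # duplicated points per cluster collapse the interval
  Xd <- rbind(matrix(rep(c(0, 0), 8), ncol = 2, byrow = TRUE),
    matrix(rep(c(9, 9), 8), ncol = 2, byrow = TRUE))
  rd <- bootstrap_indices(Xd, 2, B = 30, seed = 2, n_init = 2)
  sd_row <- rd[rd$index == "silhouette", ]
  # out-of-bag sets holding a lone point from one location score it 0 by the
  # singleton convention; every other replicate is exactly 1
  expect_equal(sd_row$value, 1)
  expect_equal(unname(sd_row$ci_upper), 1)
  expect_gte(unname(sd_row$ci_lower), 0.6)
})

test_that("k-means tidiers report per-cluster statistics and fit summaries", {
  X <- make_blobs(5, rbind(c(0, 0), c(9, 9)), sd = 0.5, seed = 11)
  km <- kmeans_lloyd(X, 2, seed = 1)
  td <- tidy(km)
  expect_equal(nrow(td), 4)  # 2 clusters x 2 dimensions
  gl <- glance(km)
  expect_equal(gl$k, 2)
  expect_equal(gl$wcss, km$wcss)
})
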