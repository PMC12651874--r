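# Internal cluster-validity indices and their out-of-bag bootstrap CIs.

#' Internal cluster-validity indices
#'
#' Textbook definitions on Euclidean distances:
#' mean silhouette `s(i) = (b - a) / max(a, b)` (singleton clusters score 0
#' by convention), Davies-Bouldin
#' `mean_i max_{j != i} (s_i + s_j) / d(c_i, c_j)` with `s_i` the mean
#' member-to-centroid distance, and Calinski-Harabasz
#' `[B / (k - 1)] / [W / (n - k)]`.
#'
#' @param X Numeric matrix or data frame.
#' @param labels Cluster labels (at least 2 nonempty clusters).
#' @return Tibble with columns `silhouette`, `davies_bouldin`,
#'   `calinski_harabasz`.
#' @export
internal_indices <- function(X, labels) {
  X <- as.matrix(as.data.frame(X))
  labels <- as.integer(factor(labels))
  k <- max(labels)
  n <- nrow(X)
  if (k < 2) stopf("indices undefined for a single cluster")
  if (any(tabulate(labels, k) == 0)) stopf("empty cluster in labels")
  d <- sqrt(pairwise_sq_dist(X))

  sizes <- tabulate(labels, k)
  sil <- vapply(seq_len(n), function(i) {
    own <- labels[i]
    if (sizes[own] == 1) return(0)
    a <- sum(d[i, labels == own]) / (sizes[own] - 1)
    b <- min(vapply(setdiff(seq_len(k), own), function(j) {
      mean(d[i, labels == j])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))

  centers <- t(vapply(seq_len(k), function(j) {
    colMeans(X[labels == j, , drop = FALSE])
  }, numeric(ncol(X))))
  if (ncol(X) == 1) centers <- matrix(centers, ncol = 1)
  scatter <- vapply(seq_len(k), function(j) {
    mean(sqrt(rowSums((X[labels == j, , drop = FALSE] -
      matrix(centers[j, ], sizes[j], ncol(X), byrow = TRUE))^2)))
  }, numeric(1))
  dc <- sqrt(pairwise_sq_dist(centers))
  db <- mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      (scatter[i] + scatter[j]) / dc[i, j]
    }, numeric(1)))
  }, numeric(1)))

  grand <- colMeans(X)
  W <- sum((X - centers[labels, , drop = FALSE])^2)
  B <- sum(sizes * rowSums((centers - matrix(grand, k, ncol(X), byrow = TRUE))^2))
  ch <- (B / (k - 1)) / (W / (n - k))

  tibble(silhouette = mean(sil), davies_bouldin = db, calinski_harabasz = ch)
}

#' Out-of-bag bootstrap confidence intervals for validity indices
#'
#' Per replicate: resample rows with replacement, fit k-means on the in-bag
#' sample, assign the out-of-bag points to their nearest centroids, and
#' compute the indices on the out-of-bag points only ("unseen data").
#' Replicates whose out-of-bag set is smaller than `k + 1` points or covers
#' fewer than 2 clusters are skipped and counted.
#'
#' @inheritParams kmeans_lloyd
#' @param B Bootstrap replicates; >= 1.
#' @return An `index_report` tibble: one row per index with the full-data
#'   `value`, percentile 95% `ci_lower`/`ci_upper`, and attributes
#'   `replicates` (kept count) and `skipped`.
#' @export
bootstrap_indices <- function(X, k, B = 200, seed = 1, n_init = 10) {
  if (B < 1) stopf("B must be >= 1")
  X <- as.matrix(as.data.frame(X))
  n <- nrow(X)
  full_fit <- kmeans_lloyd(X, k, n_init = n_init, seed = child_seed(seed, 0))
  full <- internal_indices(X, full_fit$labels)
  reps <- matrix(NA_real_, B, 3, dimnames = list(NULL, names(full)))
  skipped <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample(n, replace = TRUE)
      oob <- setdiff(seq_len(n), unique(idx))
      if (length(oob) < k + 1) { skipped <- skipped + 1L; next }
      fit <- kmeans_lloyd(X[idx, , drop = FALSE], k, n_init = n_init,
        seed = child_seed(seed, b))
      oob_labels <- assign_nearest(X[oob, , drop = FALSE], fit$centers)
      if (length(unique(oob_labels)) < 2) { skipped <- skipped + 1L; next }
      reps[b, ] <- as.numeric(internal_indices(X[oob, , drop = FALSE], oob_labels))
    }
  })
  kept <- reps[complete.cases(reps), , drop = FALSE]
  if (nrow(kept) == 0) stopf("all %d bootstrap replicates were skipped", B)
  ci <- apply(kept, 2, quantile, probs = c(0.025, 0.975), type = 7)
  out <- tibble(
    index = names(full),
    value = as.numeric(full[1, ]),
    ci_lower = ci[1, ], ci_upper = ci[2, ]
  )
  structure(out, replicates = nrow(kept), skipped = skipped, k = k,
    class = c("index_report", class(tibble())))
}
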