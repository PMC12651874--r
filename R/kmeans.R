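# Lloyd's k-means with k-means++ initialisation, best-of-n_init restarts,
# the WCSS elbow curve, and a from-scratch DBSCAN.

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
    for (j in 2:k) {
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- X[sample.int(n, 1, prob = probs), ]
      dj <- rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2)
      d2 <- pmin(d2, dj)
    }
  }
  centers
}

assign_nearest <- function(X, centers) {
  d <- outer(rowSums(X^2), rowSums(centers^2), "+") - 2 * X %*% t(centers)
  max.col(-d, ties.method = "first")
}

lloyd_once <- function(X, k, max_iter) {
  centers <- kmeanspp_init(X, k)
  labels <- assign_nearest(X, centers)
  wcss_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    for (j in seq_len(k)) {
      members <- labels == j
      if (!any(members)) {
        # re-seed an emptied cluster from the point farthest from its centre
        d <- rowSums((X - centers[labels, , drop = FALSE])^2)
        far <- which.max(d)
        centers[j, ] <- X[far, ]
        labels[far] <- j
      } else {
        centers[j, ] <- colMeans(X[members, , drop = FALSE])
      }
    }
    new_labels <- assign_nearest(X, centers)
    wcss_trace <- c(wcss_trace, sum((X - centers[new_labels, , drop = FALSE])^2))
    if (all(new_labels == labels)) { labels <- new_labels; break }
    labels <- new_labels
  }
  # final centroid update so each centroid is exactly its members' mean
  for (j in seq_len(k)) {
    members <- labels == j
    if (any(members)) centers[j, ] <- colMeans(X[members, , drop = FALSE])
  }
  wcss <- sum((X - centers[labels, , drop = FALSE])^2)
  list(labels = labels, centers = centers, wcss = wcss,
    iterations = it, wcss_trace = wcss_trace)
}

#' K-means clustering (Lloyd's algorithm, k-means++ starts)
#'
#' Runs `n_init` seeded k-means++ initialisations followed by Lloyd
#' iterations until the assignment stabilises, and keeps the run with the
#' lowest within-cluster sum of squares (WCSS).
#'
#' @param X Numeric matrix or data frame (rows = points).
#' @param k Number of clusters; `1 <= k <= n`.
#' @param n_init Number of random restarts.
#' @param seed Integer seed.
#' @param max_iter Lloyd iteration cap per restart.
#' @return A `sway_kmeans` object: `labels`, `centers`, `wcss`,
#'   `wcss_trace` (per Lloyd iteration of the best run), `k`, `n_init`,
#'   `seed`.
#' @export
kmeans_lloyd <- function(X, k, n_init = 10, seed = 1, max_iter = 100) {
  X <- as.matrix(as.data.frame(X))
  if (k > nrow(X)) stopf("k (%d) exceeds the number of points (%d)", k, nrow(X))
  if (k < 1) stopf("k must be >= 1")
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_init)) {
      run <- lloyd_once(X, k, max_iter)
      if (is.null(best) || run$wcss < best$wcss) best <- run
    }
    structure(list(
      labels = best$labels, centers = best$centers, wcss = best$wcss,
      wcss_trace = best$wcss_trace, iterations = best$iterations,
      k = k, n_init = n_init, seed = seed, X = X
    ), class = "sway_kmeans")
  })
}

#' @export
print.sway_kmeans <- function(x, ...) {
  cat(sprintf("<sway_kmeans> k = %d, n = %d, WCSS = %.4g (sizes: %s)\n",
    x$k, length(x$labels), x$wcss,
    paste(tabulate(x$labels, x$k), collapse = ", ")))
  invisible(x)
}

#' WCSS elbow curve over a range of k
#'
#' Best-of-`n_init` WCSS per candidate `k`, with an advisory knee suggestion
#' at the maximum discrete second difference of the curve (the visual elbow
#' read remains the user's call).
#'
#' @inheritParams kmeans_lloyd
#' @param k_range Integer vector of candidate cluster counts.
#' @return An `elbow_curve` tibble (`k`, `wcss`) with attribute `knee`.
#' @export
elbow_curve <- function(X, k_range = 1:8, n_init = 10, seed = 1) {
  X <- as.matrix(as.data.frame(X))
  if (any(k_range < 1 | k_range > nrow(X))) stopf("k_range must lie in [1, n]")
  k_range <- sort(unique(as.integer(k_range)))
  wcss <- vapply(seq_along(k_range), function(i) {
    kmeans_lloyd(X, k_range[i], n_init = n_init, seed = child_seed(seed, i))$wcss
  }, numeric(1))
  knee <- NA_integer_
  if (length(k_range) >= 3) {
    # discrete second difference wcss[i-1] - 2 wcss[i] + wcss[i+1]
    curv <- head(wcss, -2) - 2 * wcss[-c(1, length(wcss))] + tail(wcss, -2)
    knee <- k_range[which.max(curv) + 1L]
  }
  structure(tibble(k = k_range, wcss = wcss),
    knee = knee, class = c("elbow_curve", class(tibble())))
}

#' DBSCAN density-based clustering
#'
#' Standard density-reachability clustering. Core points have at least
#' `min_samples` neighbours (themselves included) within `eps`; clusters are
#' the connected components of core points under eps-reachability, with
#' border points attached and unreachable points labelled noise (`-1`).
#'
#' @param X Numeric matrix or data frame.
#' @param eps Neighbourhood radius; > 0.
#' @param min_samples Core-point threshold; >= 1.
#' @return Integer label vector (clusters numbered from 1; noise = -1).
#' @export
dbscan_cluster <- function(X, eps = 0.687, min_samples = 2) {
  check_number(eps, "eps", positive = TRUE)
  X <- as.matrix(as.data.frame(X))
  n <- nrow(X)
  d <- sqrt(pairwise_sq_dist(X))
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nbrs, length, integer(1)) >= min_samples
  labels <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != -1L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nbrs[[i]], i)
    while (length(queue) > 0) {
      j <- queue[1]
      queue <- queue[-1]
      if (labels[j] == -1L) {
        labels[j] <- cl
        if (core[j]) queue <- union(queue, setdiff(nbrs[[j]], which(labels != -1L)))
      }
    }
  }
  labels
}

#' Per-cluster descriptive statistics
#'
#' Per cluster and dimension: mean, sample variance (n - 1), SD, and size.
#' Singleton clusters report zero variance (flagged by `size = 1`).
#'
#' @param X Numeric matrix or data frame of coordinates.
#' @param labels Cluster label vector.
#' @return Tibble with columns `cluster`, `size`, `dimension`, `mean`,
#'   `variance`, `sd`.
#' @export
cluster_descriptives <- function(X, labels) {
  X <- as.matrix(as.data.frame(X))
  if (length(labels) != nrow(X)) stopf("labels length mismatch")
  dims <- colnames(X) %||% paste0("dim", seq_len(ncol(X)))
  colnames(X) <- dims
  out <- list()
  for (cl in sort(unique(labels))) {
    members <- X[labels == cl, , drop = FALSE]
    if (nrow(members) == 0) stopf("empty cluster %s", cl)
    v <- if (nrow(members) > 1) apply(members, 2, var) else setNames(rep(0, ncol(X)), dims)
    out[[as.character(cl)]] <- tibble(
      cluster = cl, size = nrow(members), dimension = dims,
      mean = unname(colMeans(members)), variance = unname(v), sd = sqrt(unname(v)))
  }
  bind_rows(out)
}
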