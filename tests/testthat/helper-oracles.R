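# Brute-force oracles kept deliberately independent of the implementation:
# naive double loops and exhaustive enumeration only.

# Cluster validity indices from their textbook definitions, double-loop.
oracle_indices <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.integer(factor(labels))
  n <- nrow(X)
  k <- max(labels)
  d <- as.matrix(dist(X))
  sil <- numeric(n)
  for (i in 1:n) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0) { sil[i] <- 0; next }
    a <- mean(d[i, own])
    b <- Inf
    for (cl in setdiff(1:k, labels[i])) {
      b <- min(b, mean(d[i, labels == cl]))
    }
    sil[i] <- (b - a) / max(a, b)
  }
  centers <- lapply(1:k, function(cl) colMeans(X[labels == cl, , drop = FALSE]))
  s_i <- sapply(1:k, function(cl) {
    mean(sqrt(rowSums(sweep(X[labels == cl, , drop = FALSE], 2, centers[[cl]])^2)))
  })
  db_terms <- sapply(1:k, function(i) {
    max(sapply(setdiff(1:k, i), function(j) {
      (s_i[i] + s_i[j]) / sqrt(sum((centers[[i]] - centers[[j]])^2))
    }))
  })
  grand <- colMeans(X)
  W <- sum(sapply(1:n, function(i) sum((X[i, ] - centers[[labels[i]]])^2)))
  B <- sum(sapply(1:k, function(cl) sum(labels == cl) * sum((centers[[cl]] - grand)^2)))
  list(silhouette = mean(sil), davies_bouldin = mean(db_terms),
    calinski_harabasz = (B / (k - 1)) / (W / (n - k)))
}

# Globally optimal WCSS by exhaustive enumeration of all k-labellings.
oracle_kmeans_wcss <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  best <- Inf
  labs <- rep(1L, n)
  repeat {
    if (length(unique(labs)) == k) {
      w <- 0
      for (cl in unique(labs)) {
        M <- X[labs == cl, , drop = FALSE]
        w <- w + sum(sweep(M, 2, colMeans(M))^2)
      }
      best <- min(best, w)
    }
    i <- 1L
    while (i <= n && labs[i] == k) { labs[i] <- 1L; i <- i + 1L }
    if (i > n) break
    labs[i] <- labs[i] + 1L
  }
  best
}

# DBSCAN by explicit reachability closure.
oracle_dbscan <- function(X, eps, min_samples) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- as.matrix(dist(X))
  core <- sapply(1:n, function(i) sum(d[i, ] <= eps) >= min_samples)
  lab <- rep(-1L, n)
  cl <- 0L
  for (i in 1:n) {
    if (!core[i] || lab[i] != -1L) next
    cl <- cl + 1L
    member <- rep(FALSE, n)
    member[i] <- TRUE
    repeat {
      grew <- FALSE
      for (j in which(member & core)) {
        reach <- which(d[j, ] <= eps & !member)
        if (length(reach) > 0) { member[reach] <- TRUE; grew <- TRUE }
      }
      if (!grew) break
    }
    lab[member & lab == -1L] <- cl
  }
  lab
}

# Shapley values by averaging marginal contributions over all d! orderings.
oracle_shapley <- function(predict_fn, instance, background, feature_names) {
  d <- length(feature_names)
  bg <- as.matrix(background)[, feature_names, drop = FALSE]
  v <- function(S) {
    Z <- bg
    if (length(S) > 0) Z[, S] <- matrix(unlist(instance[S]), nrow(Z), length(S), byrow = TRUE)
    colnames(Z) <- feature_names
    mean(predict_fn(Z))
  }
  perms <- gtools_permutations(d)
  phi <- setNames(numeric(d), feature_names)
  for (p in seq_len(nrow(perms))) {
    S <- character(0)
    for (i in perms[p, ]) {
      f <- feature_names[i]
      phi[f] <- phi[f] + v(c(S, f)) - v(S)
      S <- c(S, f)
    }
  }
  phi / nrow(perms)
}

# All permutations of 1..d without external packages.
gtools_permutations <- function(d) {
  if (d == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(d - 1)
  out <- NULL
  for (i in 1:d) {
    out <- rbind(out, cbind(i, matrix(setdiff(1:d, i)[sub], nrow(sub))))
  }
  unname(out)
}

# Isotropic Gaussian blobs.
make_blobs <- function(n_per, centers, sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
        matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)
    }))
  })
}

# Small standing-only study cohort used across tests (reduced sampling rate).
tiny_cohort <- function(seed = 1, fs = 125, ...) {
  simulate_cohort(cohort_config(fs = fs, ...), seed = seed)
}
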