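# t-distributed stochastic neighbour embedding, implemented from scratch:
# per-point Gaussian bandwidths calibrated to a target perplexity by
# bisection, joint similarities by symmetrisation, and gradient descent on
# the Kullback-Leibler divergence with a Student-t low-dimensional kernel.

#' High-dimensional affinity matrix for t-SNE
#'
#' For each point, the Gaussian bandwidth `sigma_i` is found by bisection so
#' that the Shannon perplexity `exp(H(P_i))` of the conditional neighbour
#' distribution matches the target. Conditionals are then symmetrised to the
#' joint matrix `P = (P_cond + t(P_cond)) / (2n)` (the standard
#' construction). The alternative `"joint"` form normalises the per-point
#' Gaussian kernels by a single global sum and symmetrises.
#'
#' @param X Numeric matrix or data frame (rows = points).
#' @param perplexity Target perplexity; `1 <= perplexity < n`.
#' @param affinity `"conditional_symmetrized"` (default) or `"joint"`.
#' @param tol Bisection tolerance on the achieved perplexity.
#' @param jitter_duplicates Add tiny jitter when duplicate points collapse
#'   distances to zero; error if `FALSE` and duplicates exist.
#' @return An `affinity_matrices` list: `P` (joint, rows+cols sum to 1),
#'   `sigma`, `achieved_perplexity`, `X`, `perplexity`.
#' @export
tsne_affinities <- function(X, perplexity = 2,
                            affinity = c("conditional_symmetrized", "joint"),
                            tol = 1e-5, jitter_duplicates = FALSE) {
  affinity <- match.arg(affinity)
  X <- as.matrix(as.data.frame(X))
  n <- nrow(X)
  if (n < 3) stopf("t-SNE needs n >= 3 points (got %d)", n)
  if (perplexity >= n) stopf("perplexity (%g) must be < n (%d)", perplexity, n)
  d2 <- pairwise_sq_dist(X)
  off <- d2[upper.tri(d2)]
  if (any(off == 0)) {
    if (!jitter_duplicates) stopf("duplicate points collapse distances; set jitter_duplicates = TRUE")
    X <- X + matrix(rnorm(length(X), 0, 1e-8 * (max(X) - min(X) + 1)), nrow = n)
    d2 <- pairwise_sq_dist(X)
  }
  target_h <- log(perplexity)
  sigma <- numeric(n)
  P_cond <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    # bisection on log2(precision) beta = 1 / (2 sigma^2)
    lo <- -60; hi <- 60
    for (iter in 1:200) {
      beta <- 2^((lo + hi) / 2)
      w <- exp(-di * beta)
      s <- sum(w)
      if (s <= 0) { hi <- (lo + hi) / 2; next }
      p <- w / s
      h <- -sum(ifelse(p > 0, p * log(p), 0))
      if (abs(h - target_h) < tol * max(1, abs(target_h))) break
      if (h > target_h) lo <- (lo + hi) / 2 else hi <- (lo + hi) / 2
    }
    sigma[i] <- 1 / sqrt(2 * beta)
    P_cond[i, -i] <- p
  }
  achieved <- vapply(seq_len(n), function(i) {
    p <- P_cond[i, -i]
    exp(-sum(ifelse(p > 0, p * log(p), 0)))
  }, numeric(1))
  P <- if (affinity == "conditional_symmetrized") {
    (P_cond + t(P_cond)) / (2 * n)
  } else {
    W <- exp(-d2 / (2 * sigma^2))  # sigma_i by row, as in the joint form
    diag(W) <- 0
    W <- W / sum(W)
    (W + t(W)) / 2
  }
  P <- pmax(P, .Machine$double.xmin)
  diag(P) <- 0
  structure(list(
    P = P, sigma = sigma, achieved_perplexity = achieved,
    perplexity = perplexity, affinity = affinity, X = X
  ), class = "affinity_matrices")
}

# Student-t joint similarities and KL divergence for an embedding Y.
tsne_q <- function(Y) {
  num <- 1 / (1 + pairwise_sq_dist(Y))
  diag(num) <- 0
  list(Q = pmax(num / sum(num), .Machine$double.xmin), num = num)
}

tsne_kl <- function(P, Q) {
  idx <- P > .Machine$double.xmin
  max(0, sum(P[idx] * log(P[idx] / Q[idx])))
}

#' Optimise a 2-D t-SNE embedding
#'
#' Gradient descent on `KL(P || Q)` with the Student-t kernel in the
#' embedding space, momentum switching, and early exaggeration of `P`.
#' Deterministic under a fixed seed (which controls the random Gaussian
#' initialisation).
#'
#' @param affinities A [tsne_affinities()] result.
#' @param seed Integer seed for the initialisation.
#' @param iters Gradient-descent iterations.
#' @param learning_rate Step size; `"auto"` uses `max(n / 12, 10)`,
#'   sized down for the tiny cohorts this package targets.
#' @param momentum Length-2 vector: momentum before and after
#'   `momentum_switch`.
#' @param momentum_switch Iteration at which momentum switches.
#' @param early_exaggeration Factor multiplying `P` for the first
#'   `exaggeration_iters` iterations.
#' @param exaggeration_iters Length of the early-exaggeration phase.
#' @return A `sway_tsne` object: `Y` (n x 2), `kl_trace` (KL against the
#'   un-exaggerated `P` at every iteration), `Q`, and the schedule
#'   parameters. `KL >= 0` always and the final KL is below the initial KL.
#' @export
tsne_embed <- function(affinities, seed = 42, iters = 1000,
                       learning_rate = "auto", momentum = c(0.5, 0.8),
                       momentum_switch = 250, early_exaggeration = 4,
                       exaggeration_iters = 100) {
  P <- affinities$P
  n <- nrow(P)
  eta <- if (identical(learning_rate, "auto")) max(n / 12, 10) else learning_rate
  with_seed(seed, {
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
    V <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    kl_trace <- numeric(iters)
    best_Y <- Y
    best_kl <- Inf
    for (it in seq_len(iters)) {
      Pe <- if (it <= exaggeration_iters) P * early_exaggeration else P
      q <- tsne_q(Y)
      kl_trace[it] <- tsne_kl(P, q$Q)
      if (is.nan(kl_trace[it]) || !is.finite(kl_trace[it])) {
        stopf("t-SNE diverged at iteration %d (eta = %g, exaggeration = %g)",
          it, eta, early_exaggeration)
      }
      if (kl_trace[it] < best_kl) { best_kl <- kl_trace[it]; best_Y <- Y }
      M <- (Pe - q$Q) * q$num
      grad <- 4 * (diag(rowSums(M)) %*% Y - M %*% Y)
      mom <- if (it < momentum_switch) momentum[1] else momentum[2]
      gains <- ifelse(sign(grad) != sign(V), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      V <- mom * V - eta * gains * grad
      Y <- Y + V
      Y <- sweep(Y, 2, colMeans(Y))
    }
    q <- tsne_q(best_Y)
    structure(list(
      Y = best_Y, kl_trace = kl_trace, final_kl = best_kl, Q = q$Q,
      perplexity = affinities$perplexity, seed = seed, iters = iters,
      learning_rate = eta, momentum = momentum,
      early_exaggeration = early_exaggeration
    ), class = "sway_tsne")
  })
}

#' @export
print.sway_tsne <- function(x, ...) {
  cat(sprintf("<sway_tsne> n = %d, perplexity = %g, KL %.4f -> %.4f (%d iters)\n",
    nrow(x$Y), x$perplexity, x$kl_trace[1], x$final_kl, x$iters))
  invisible(x)
}

#' One-call t-SNE embedding
#'
#' @inheritParams tsne_affinities
#' @inheritParams tsne_embed
#' @param ... Passed to [tsne_embed()].
#' @return A `sway_tsne` object.
#' @export
tsne <- function(X, perplexity = 2, seed = 42, ...) {
  tsne_embed(tsne_affinities(X, perplexity = perplexity), seed = seed, ...)
}
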