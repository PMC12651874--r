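# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`, leaving the
# caller's RNG untouched. All randomness in the package funnels through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a child seed from a parent seed and a stream index, staying inside
# the 32-bit signed integer range.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1103515245 + 12345 * as.double(index)) %% 2147483647)
}

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))

check_number <- function(x, name, positive = FALSE, non_negative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  if (positive && x <= 0) stopf("`%s` must be > 0 (got %g)", name, x)
  if (non_negative && x < 0) stopf("`%s` must be >= 0 (got %g)", name, x)
  invisible(x)
}

# Pairwise squared Euclidean distances as a dense matrix.
pairwise_sq_dist <- function(X) {
  X <- as.matrix(X)
  s <- rowSums(X^2)
  d2 <- outer(s, s, "+") - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  d2
}
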