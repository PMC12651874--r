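# Wrapper classifiers used by forward feature selection: an L2-penalised
# logistic regression (hand-written IRLS; the ridge penalty keeps the fit
# defined under the perfect separation that tiny cohorts readily produce)
# and k-nearest neighbours via class::knn.

#' Classifier specification
#'
#' @param kind `"logistic_regression"` or `"k_nearest_neighbors"`.
#' @param k Neighbour count for KNN; odd and >= 1.
#' @param lambda L2 regularisation strength for logistic regression
#'   (penalty `lambda/2 * ||beta||^2` on the non-intercept coefficients).
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(kind = c("logistic_regression", "k_nearest_neighbors"),
                            k = 5, lambda = 1) {
  kind <- match.arg(kind)
  if (kind == "k_nearest_neighbors") {
    if (k < 1 || k %% 2 != 1) stopf("KNN `k` must be odd and >= 1 (got %g)", k)
  }
  check_number(lambda, "lambda", non_negative = TRUE)
  structure(list(kind = kind, k = k, lambda = lambda), class = "classifier_spec")
}

# Ridge logistic regression by iteratively reweighted least squares.
# y in {0,1}; the intercept is unpenalised.
ridge_logistic <- function(x, y, lambda = 1, max_iter = 50, tol = 1e-8) {
  x <- as.matrix(x)
  X <- cbind(1, x)
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    A <- crossprod(X * w, X) + pen
    b <- crossprod(X * w, z)
    beta_new <- drop(solve(A, b))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  list(beta = beta, iterations = it)
}

# Fit a classifier; returns an object usable by predict_classifier().
fit_classifier <- function(x, y, spec) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (spec$kind == "logistic_regression") {
    fit <- ridge_logistic(x, y, lambda = spec$lambda)
    structure(list(spec = spec, beta = fit$beta), class = "swayshift_lr")
  } else {
    structure(list(spec = spec, x = x, y = y), class = "swayshift_knn")
  }
}

# Predicted probability of class 1 (LR) or hard votes mapped to {0,1} (KNN).
predict_classifier <- function(model, newx, type = c("class", "prob")) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  if (inherits(model, "swayshift_lr")) {
    prob <- 1 / (1 + exp(-drop(cbind(1, newx) %*% model$beta)))
    if (type == "prob") prob else as.integer(prob >= 0.5)
  } else {
    k <- min(model$spec$k, nrow(model$x))
    cl <- class::knn(model$x, newx, factor(model$y, levels = c(0, 1)),
      k = k, prob = (type == "prob"))
    if (type == "class") {
      as.integer(as.character(cl))
    } else {
      pr <- attr(cl, "prob")
      ifelse(cl == "1", pr, 1 - pr)
    }
  }
}

# Stratified k-fold assignment (deterministic given the RNG state).
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# k-fold cross-validated accuracy of `spec` on feature matrix x.
cv_accuracy <- function(x, y, spec, folds) {
  x <- as.matrix(x)
  correct <- 0L
  for (f in sort(unique(folds))) {
    test <- folds == f
    if (length(unique(y[!test])) < 2) {
      stopf("a training fold contains a single class")
    }
    model <- fit_classifier(x[!test, , drop = FALSE], y[!test], spec)
    pred <- predict_classifier(model, x[test, , drop = FALSE], type = "class")
    correct <- correct + sum(pred == y[test])
  }
  correct / length(y)
}
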