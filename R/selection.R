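# Forward feature selection with wrapper classifiers, nested
# cross-validation, bootstrap confidence intervals and permutation tests.

# Evaluation metric on a prediction vector / probability vector.
metric_value <- function(metric, y, pred, prob = NULL) {
  switch(metric,
    accuracy = mean(pred == y),
    f1 = {
      tp <- sum(pred == 1 & y == 1)
      fp <- sum(pred == 1 & y == 0)
      fn <- sum(pred == 0 & y == 1)
      if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    },
    auc = {
      pos <- prob[y == 1]
      neg <- prob[y == 0]
      if (length(pos) == 0 || length(neg) == 0) NA_real_
      else (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
        (length(pos) * length(neg))
    },
    stopf("unknown metric '%s'", metric))
}

as_binary_labels <- function(labels) {
  u <- sort(unique(labels))
  if (length(u) != 2) stopf("labels must be binary (got %d levels)", length(u))
  as.integer(labels == u[2])
}

#' Greedy forward feature selection
#'
#' Starting from the empty set, repeatedly adds the candidate feature that
#' maximises inner cross-validated accuracy of the wrapper classifier,
#' until `target_size` features are selected. Ties are broken by column
#' order and logged.
#'
#' @param data Tibble or matrix of candidate features (numeric columns).
#' @param labels Binary label vector (two levels; the second sorted level is
#'   coded 1).
#' @param spec A [classifier_spec()].
#' @param target_size Number of features to select; <= `ncol(data)`.
#' @param inner_folds Stratified fold count of the inner CV.
#' @param cv_repeats Number of repeated fold assignments averaged per
#'   candidate score; repetition stabilises the greedy criterion on the
#'   small cohorts this package targets.
#' @param seed Integer seed for fold assignment.
#' @return A `selection_result`: list with `selected` (ordered names),
#'   `trace` (tibble: step, feature, score), `ties` (list of tied
#'   candidates per step), `spec`.
#' @export
forward_select <- function(data, labels, spec = classifier_spec(),
                           target_size = 3, inner_folds = 3, cv_repeats = 8,
                           seed = 1) {
  x <- as.matrix(as.data.frame(data))
  y <- as_binary_labels(labels)
  if (target_size > ncol(x)) stopf("target_size %d > %d features", target_size, ncol(x))
  if (nrow(x) < inner_folds) stopf("fewer rows (%d) than folds (%d)", nrow(x), inner_folds)
  folds <- with_seed(seed, lapply(seq_len(cv_repeats), function(r) {
    stratified_folds(y, inner_folds)
  }))
  selected <- character(0)
  trace <- list()
  ties <- list()
  candidates <- colnames(x)
  step <- 0L
  while (length(selected) < target_size) {
    step <- step + 1L
    pool <- setdiff(candidates, selected)
    scores <- vapply(pool, function(f) {
      mean(vapply(folds, function(fd) {
        cv_accuracy(x[, c(selected, f), drop = FALSE], y, spec, fd)
      }, numeric(1)))
    }, numeric(1))
    best <- max(scores)
    tied <- pool[scores == best]
    pick <- tied[1]
    if (length(tied) > 1) ties[[as.character(step)]] <- tied
    selected <- c(selected, pick)
    trace[[step]] <- tibble(step = step, feature = pick, score = best)
  }
  structure(list(
    selected = selected,
    trace = if (step > 0) bind_rows(trace) else tibble(step = integer(), feature = character(), score = numeric()),
    ties = ties, spec = spec
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>", paste(x$selected, collapse = " -> "), "\n")
  print(x$trace)
  invisible(x)
}

#' Nested cross-validation of the selection-plus-classifier pipeline
#'
#' Outer folds leave one group (subject) out, so pre/post sessions of one
#' subject never straddle the train/test split; feature selection is re-run
#' inside each outer training fold and the selected model is scored on the
#' held-out group.
#'
#' @inheritParams forward_select
#' @param groups Grouping vector (e.g. subject ids) defining the outer
#'   leave-one-group-out folds.
#' @param metric `"accuracy"`, `"f1"` or `"auc"`.
#' @return A `validation_report` with per-fold scores, their mean and SD,
#'   and the per-fold selections.
#' @export
nested_cv_evaluate <- function(data, labels, groups, spec = classifier_spec(),
                               target_size = 3, inner_folds = 3,
                               cv_repeats = 8, seed = 1,
                               metric = "accuracy") {
  x <- as.matrix(as.data.frame(data))
  y <- as_binary_labels(labels)
  gs <- unique(groups)
  scores <- numeric(0)
  selections <- list()
  for (i in seq_along(gs)) {
    test <- groups == gs[i]
    ytr <- y[!test]
    if (length(unique(ytr)) < 2) stopf("outer training fold for group '%s' has one class", gs[i])
    sel <- forward_select(x[!test, , drop = FALSE], ytr, spec,
      target_size = target_size, inner_folds = inner_folds,
      cv_repeats = cv_repeats, seed = child_seed(seed, i))
    model <- fit_classifier(x[!test, sel$selected, drop = FALSE], ytr, spec)
    pred <- predict_classifier(model, x[test, sel$selected, drop = FALSE], "class")
    prob <- predict_classifier(model, x[test, sel$selected, drop = FALSE], "prob")
    scores[i] <- metric_value(metric, y[test], pred, prob)
    selections[[as.character(gs[i])]] <- sel$selected
  }
  structure(list(
    metric = metric, scores = scores,
    mean = mean(scores, na.rm = TRUE), sd = sd(scores),
    selections = selections, n_folds = length(gs)
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s = %.3f +/- %.3f over %d folds/replicates\n",
    x$metric, x$mean, if (is.na(x$sd)) 0 else x$sd,
    x$n_folds %||% length(x$scores)))
  if (!is.null(x$ci)) cat(sprintf("  95%% CI [%.3f, %.3f]\n", x$ci[1], x$ci[2]))
  if (!is.null(x$p_value)) cat(sprintf("  permutation p = %.4g\n", x$p_value))
  invisible(x)
}

# Shared evaluation used by bootstrap_metrics / permutation_test: accuracy
# (or other metric) of `spec` on the selected features, either through
# stratified k-fold CV predictions or through a pre-fitted model.
holdout_metric <- function(x, y, spec, metric, folds) {
  pred <- integer(length(y))
  prob <- numeric(length(y))
  for (f in sort(unique(folds))) {
    test <- folds == f
    model <- fit_classifier(x[!test, , drop = FALSE], y[!test], spec)
    pred[test] <- predict_classifier(model, x[test, , drop = FALSE], "class")
    prob[test] <- predict_classifier(model, x[test, , drop = FALSE], "prob")
  }
  metric_value(metric, y, pred, prob)
}

#' Bootstrap confidence interval for a classification metric
#'
#' Case-resampling bootstrap: each replicate resamples rows with
#' replacement and recomputes the metric. With `model = NULL` the
#' classifier is fitted once on the full data and each replicate scores its
#' predictions on the resampled cases; passing a pre-fitted model (from an
#' independent training set) scores that model instead. Replicates whose
#' resample contains a single class are redrawn (counted, capped at
#' `10 * B` total draws).
#'
#' @inheritParams forward_select
#' @param selected Character vector of feature columns to use.
#' @param B Number of bootstrap replicates; >= 1.
#' @param metric `"accuracy"`, `"f1"` or `"auc"`.
#' @param model Optional pre-fitted classifier (see [forward_select()]
#'   internals); fitted on `data[selected]` when `NULL`.
#' @return A `validation_report` with the replicate values, the point
#'   estimate on the full data, and the percentile 95% CI.
#' @export
bootstrap_metrics <- function(data, labels, spec = classifier_spec(),
                              selected = colnames(data), B = 1000, seed = 1,
                              metric = "accuracy", model = NULL) {
  if (B < 1) stopf("B must be >= 1")
  x <- as.matrix(as.data.frame(data))[, selected, drop = FALSE]
  y <- as_binary_labels(labels)
  if (is.null(model)) model <- fit_classifier(x, y, spec)
  score <- function(idx) {
    pred <- predict_classifier(model, x[idx, , drop = FALSE], "class")
    prob <- predict_classifier(model, x[idx, , drop = FALSE], "prob")
    metric_value(metric, y[idx], pred, prob)
  }
  point <- score(seq_along(y))
  with_seed(seed, {
    vals <- numeric(B)
    redraws <- 0L
    for (b in seq_len(B)) {
      repeat {
        idx <- sample(length(y), replace = TRUE)
        if (length(unique(y[idx])) == 2 || metric == "accuracy") break
        redraws <- redraws + 1L
        if (redraws > 10L * B) stopf("too many single-class resamples")
      }
      vals[b] <- score(idx)
    }
    ci <- unname(quantile(vals, c(0.025, 0.975), type = 7))
    structure(list(
      metric = metric, scores = vals, mean = point, sd = sd(vals),
      ci = ci, B = B, redraws = redraws, seed = seed
    ), class = "validation_report")
  })
}

#' Permutation test of a classification metric
#'
#' The observed metric is the stratified `folds`-fold cross-validated value
#' on the true labels; each of `B` permutations shuffles the labels and
#' recomputes it. The p-value uses the add-one rule
#' `p = (1 + #(permuted >= observed)) / (B + 1)`.
#'
#' @inheritParams bootstrap_metrics
#' @param B Number of permutations; >= 19.
#' @param folds Stratified CV folds for the metric evaluation.
#' @return A `validation_report` with `p_value`, the observed value
#'   (`mean`), and the permutation distribution (`scores`).
#' @export
permutation_test <- function(data, labels, spec = classifier_spec(),
                             selected = colnames(data), B = 199, seed = 1,
                             metric = "accuracy", folds = 3) {
  if (B < 19) stopf("B must be >= 19")
  x <- as.matrix(as.data.frame(data))[, selected, drop = FALSE]
  y <- as_binary_labels(labels)
  with_seed(seed, {
    fold_id <- stratified_folds(y, folds)
    observed <- holdout_metric(x, y, spec, metric, fold_id)
    perm <- numeric(B)
    for (b in seq_len(B)) {
      yp <- sample(y)
      perm[b] <- holdout_metric(x, yp, spec, metric, stratified_folds(yp, folds))
    }
    p <- (1 + sum(perm >= observed)) / (B + 1)
    structure(list(
      metric = metric, scores = perm, mean = observed, sd = sd(perm),
      p_value = p, B = B, seed = seed
    ), class = "validation_report")
  })
}

#' McFadden pseudo-R-squared of a logistic model
#'
#' `1 - logLik(model) / logLik(intercept-only)` for a maximum-likelihood
#' logistic regression of the binary labels on the selected features. Under
#' (quasi-)perfect separation the unpenalised likelihood is unbounded; the
#' value is then computed from a lightly ridge-penalised fit and flagged via
#' the `"separation"` attribute.
#'
#' @inheritParams bootstrap_metrics
#' @return Numeric scalar with attribute `separation` (logical).
#' @export
mcfadden_r2 <- function(data, labels, selected = colnames(data)) {
  x <- as.data.frame(data)[, selected, drop = FALSE]
  y <- as_binary_labels(labels)
  df <- cbind(data.frame(.y = y), x)
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  loglik <- function(p) sum(y * log(p) + (1 - y) * log(1 - p))
  if (separated) {
    rl <- ridge_logistic(as.matrix(x), y, lambda = 1e-3)
    p_hat <- 1 / (1 + exp(-drop(cbind(1, as.matrix(x)) %*% rl$beta)))
    ll_model <- loglik(pmin(pmax(p_hat, 1e-12), 1 - 1e-12))
  } else {
    ll_model <- loglik(pmin(pmax(fitted(fit), 1e-12), 1 - 1e-12))
  }
  p0 <- mean(y)
  ll_null <- sum(y) * log(p0) + sum(1 - y) * log(1 - p0)
  out <- 1 - ll_model / ll_null
  attr(out, "separation") <- separated
  out
}

#' Dual-wrapper selected feature vector
#'
#' Runs forward selection under both wrapper classifiers (logistic
#' regression and KNN) and merges the two selections into a single feature
#' vector: features are ranked by how many wrappers selected them, then by
#' their earliest selection step, and the top `size` are kept. This mirrors
#' the reporting of per-estimator selections plus their consensus.
#'
#' @inheritParams forward_select
#' @param size Number of features in the merged vector.
#' @param lr_spec,knn_spec The two wrapper [classifier_spec()]s.
#' @return A `selection_result` whose `selected` is the merged vector;
#'   `per_estimator` holds both underlying results.
#' @export
select_feature_vector <- function(data, labels, size = 3,
                                  target_size = 3, inner_folds = 3,
                                  cv_repeats = 8, seed = 1,
                                  lr_spec = classifier_spec("logistic_regression"),
                                  knn_spec = classifier_spec("k_nearest_neighbors")) {
  sel_lr <- forward_select(data, labels, lr_spec, target_size = target_size,
    inner_folds = inner_folds, cv_repeats = cv_repeats,
    seed = child_seed(seed, 1))
  sel_knn <- forward_select(data, labels, knn_spec, target_size = target_size,
    inner_folds = inner_folds, cv_repeats = cv_repeats,
    seed = child_seed(seed, 2))
  feats <- union(sel_lr$selected, sel_knn$selected)
  votes <- vapply(feats, function(f) {
    (f %in% sel_lr$selected) + (f %in% sel_knn$selected)
  }, numeric(1))
  step <- vapply(feats, function(f) {
    min(match(f, sel_lr$selected, nomatch = target_size + 1L),
        match(f, sel_knn$selected, nomatch = target_size + 1L))
  }, numeric(1))
  ord <- order(-votes, step, match(feats, colnames(as.data.frame(data))))
  merged <- feats[ord][seq_len(min(size, length(feats)))]
  structure(list(
    selected = merged,
    trace = tibble(step = seq_along(merged), feature = merged,
      score = NA_real_),
    ties = list(),
    per_estimator = list(logistic_regression = sel_lr,
      k_nearest_neighbors = sel_knn),
    spec = list(lr = lr_spec, knn = knn_spec)
  ), class = "selection_result")
}
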