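# Exact Shapley attribution by full coalition enumeration with an
# interventional value function: absent features are marginalised over a
# background sample, v(S) = mean_z f(x_S union z_notS).

#' Exact Shapley attribution for one instance
#'
#' Enumerates all `2^d` coalitions (d <= 12) and computes
#' `phi_i = sum_S |S|! (d - |S| - 1)! / d! * (v(S + i) - v(S))` with the
#' interventional value function. Additivity
#' `sum(phi) = f(instance) - base_value` holds by construction and is
#' asserted to 1e-9.
#'
#' @param predict_fn Function mapping a numeric matrix (columns =
#'   `feature_names`) to a numeric prediction vector.
#' @param instance Named numeric vector (the explained point).
#' @param background Matrix or data frame of background rows used to
#'   marginalise absent features.
#' @param feature_names Features to attribute; defaults to
#'   `names(instance)`.
#' @return A `shapley_report`: `phi` (named), `base_value` (mean prediction
#'   over the background), `prediction`, `instance`.
#' @export
exact_shapley <- function(predict_fn, instance, background,
                          feature_names = names(instance)) {
  d <- length(feature_names)
  if (d > 12) stopf("exact enumeration supports at most 12 features (got %d)", d)
  background <- as.matrix(as.data.frame(background))[, feature_names, drop = FALSE]
  if (nrow(background) == 0) stopf("background set is empty")
  x <- unlist(instance[feature_names])

  # v(S) for every subset, encoded as bitmask 0 .. 2^d - 1
  n_sub <- 2^d
  v <- numeric(n_sub)
  for (mask in 0:(n_sub - 1)) {
    Z <- background
    in_s <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(d) - 1L)) != 0L)
    if (length(in_s) > 0) {
      Z[, in_s] <- matrix(x[in_s], nrow(Z), length(in_s), byrow = TRUE)
    }
    colnames(Z) <- feature_names
    v[mask + 1L] <- mean(predict_fn(Z))
  }

  fact <- factorial(0:d)
  phi <- setNames(numeric(d), feature_names)
  for (i in seq_len(d)) {
    bit_i <- bitwShiftL(1L, i - 1L)
    for (mask in 0:(n_sub - 1)) {
      if (bitwAnd(mask, bit_i) != 0L) next
      s <- sum(bitwAnd(mask, bitwShiftL(1L, seq_len(d) - 1L)) != 0L)
      w <- fact[s + 1L] * fact[d - s] / fact[d + 1L]
      phi[i] <- phi[i] + w * (v[mask + bit_i + 1L] - v[mask + 1L])
    }
  }
  base_value <- v[1]
  prediction <- v[n_sub]
  if (abs(sum(phi) - (prediction - base_value)) > 1e-9) {
    stopf("Shapley additivity violated: sum(phi) = %g vs f - base = %g",
      sum(phi), prediction - base_value)
  }
  structure(list(phi = phi, base_value = base_value, prediction = prediction,
    instance = x), class = "shapley_report")
}

#' @export
print.shapley_report <- function(x, ...) {
  cat(sprintf("<shapley_report> base %.4f -> prediction %.4f\n",
    x$base_value, x$prediction))
  print(round(x$phi, 4))
  invisible(x)
}

#' Summarise Shapley reports across instances
#'
#' @param reports List of [exact_shapley()] reports over a consistent
#'   feature set.
#' @return A `shapley_summary` list: `ranking` (tibble: feature,
#'   mean_abs_phi, sorted descending) and `dependence` (tibble: feature,
#'   value, phi - one row per instance and feature).
#' @export
shap_summary <- function(reports) {
  feats <- names(reports[[1]]$phi)
  for (r in reports) {
    if (!identical(names(r$phi), feats)) stopf("inconsistent feature sets across reports")
  }
  dep <- bind_rows(lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    tibble(instance = i, feature = feats,
      value = unname(r$instance[feats]), phi = unname(r$phi))
  }))
  ranking <- dep |>
    group_by(.data$feature) |>
    summarise(mean_abs_phi = mean(abs(.data$phi)), .groups = "drop") |>
    arrange(dplyr::desc(.data$mean_abs_phi))
  structure(list(ranking = ranking, dependence = dep), class = "shapley_summary")
}

#' @export
print.shapley_summary <- function(x, ...) {
  cat("<shapley_summary>\n")
  print(x$ranking)
  invisible(x)
}

#' Shapley explanation of a logistic model on selected features
#'
#' Fits the package's L2-penalised logistic regression of the binary labels
#' on the selected features and explains the predicted probability of every
#' instance by exact Shapley attribution, with the analysis table itself as
#' the background.
#'
#' @inheritParams bootstrap_metrics
#' @param lambda Ridge strength of the explained logistic model.
#' @return A [shap_summary()] result.
#' @export
shap_logistic <- function(data, labels, selected = colnames(data), lambda = 1) {
  x <- as.matrix(as.data.frame(data))[, selected, drop = FALSE]
  y <- as_binary_labels(labels)
  model <- fit_classifier(x, y, classifier_spec("logistic_regression", lambda = lambda))
  predict_fn <- function(m) predict_classifier(model, m[, selected, drop = FALSE], "prob")
  reports <- lapply(seq_len(nrow(x)), function(i) {
    exact_shapley(predict_fn, setNames(x[i, ], selected), x, selected)
  })
  shap_summary(reports)
}
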