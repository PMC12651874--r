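# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a k-means fit into per-cluster statistics
#'
#' @param x A [kmeans_lloyd()] result.
#' @param ... Unused.
#' @return Tibble: one row per cluster and dimension with mean, variance,
#'   SD, size (the cluster-descriptives report shape).
#' @export
tidy.sway_kmeans <- function(x, ...) {
  cluster_descriptives(x$X, x$labels)
}

#' @rdname tidy.sway_kmeans
#' @return `glance()`: one-row tibble with `k`, `n`, `wcss`, `iterations`.
#' @export
glance.sway_kmeans <- function(x, ...) {
  tibble(k = x$k, n = length(x$labels), wcss = x$wcss,
    iterations = x$iterations)
}

#' Tidy a t-SNE embedding
#'
#' @param x A [tsne_embed()] result.
#' @param ... Unused.
#' @return Tibble with `point`, `tsne_1`, `tsne_2`.
#' @export
tidy.sway_tsne <- function(x, ...) {
  tibble(point = seq_len(nrow(x$Y)), tsne_1 = x$Y[, 1], tsne_2 = x$Y[, 2])
}

#' @rdname tidy.sway_tsne
#' @return `glance()`: one-row tibble with `n`, `perplexity`,
#'   `initial_kl`, `final_kl`, `iters`.
#' @export
glance.sway_tsne <- function(x, ...) {
  tibble(n = nrow(x$Y), perplexity = x$perplexity,
    initial_kl = x$kl_trace[1], final_kl = x$final_kl, iters = x$iters)
}

#' Tidy a Shapley report
#'
#' @param x An [exact_shapley()] report.
#' @param ... Unused.
#' @return Tibble with `feature`, `value`, `phi`.
#' @export
tidy.shapley_report <- function(x, ...) {
  tibble(feature = names(x$phi), value = unname(x$instance[names(x$phi)]),
    phi = unname(x$phi))
}

#' Tidy a validation report
#'
#' @param x A `validation_report` (nested CV, bootstrap, or permutation).
#' @param ... Unused.
#' @return Tibble of replicate/fold scores.
#' @export
tidy.validation_report <- function(x, ...) {
  tibble(replicate = seq_along(x$scores), score = x$scores)
}

#' @rdname tidy.validation_report
#' @return `glance()`: one-row tibble with the point estimate, SD, CI
#'   bounds and p-value where available.
#' @export
glance.validation_report <- function(x, ...) {
  tibble(metric = x$metric, estimate = x$mean, sd = x$sd,
    ci_lower = if (is.null(x$ci)) NA_real_ else x$ci[1],
    ci_upper = if (is.null(x$ci)) NA_real_ else x$ci[2],
    p_value = x$p_value %||% NA_real_)
}
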