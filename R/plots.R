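# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_text
#'   geom_col geom_vline labs theme_minimal coord_equal
#' @export
ggplot2::autoplot

#' Plot a t-SNE embedding
#'
#' @param object A [tsne_embed()] result.
#' @param labels Optional point labels (e.g. [subject_labels()]).
#' @param clusters Optional cluster assignment used for colour.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sway_tsne <- function(object, labels = NULL, clusters = NULL, ...) {
  df <- tidy.sway_tsne(object)
  if (!is.null(clusters)) df$cluster <- factor(clusters)
  p <- ggplot(df, aes(x = .data$tsne_1, y = .data$tsne_2)) +
    theme_minimal() +
    labs(x = "t-SNE 1", y = "t-SNE 2",
      title = sprintf("t-SNE embedding (perplexity %g)", object$perplexity))
  p <- if (is.null(clusters)) {
    p + geom_point(size = 2)
  } else {
    p + geom_point(aes(colour = .data$cluster), size = 2)
  }
  if (!is.null(labels)) {
    df$label <- labels
    p <- p + geom_text(data = df, aes(label = .data$label),
      vjust = -0.8, size = 2.7)
  }
  p
}

#' Plot an elbow curve
#'
#' @param object An [elbow_curve()] result.
#' @param ... Unused.
#' @return A ggplot object with the advisory knee marked.
#' @export
autoplot.elbow_curve <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$k, y = .data$wcss)) +
    geom_line() + geom_point() + theme_minimal() +
    labs(x = "k", y = "WCSS", title = "Elbow curve")
  knee <- attr(object, "knee")
  if (!is.na(knee)) p <- p + geom_vline(xintercept = knee, linetype = "dashed")
  p
}

#' Plot a Shapley summary
#'
#' @param object A [shap_summary()] result.
#' @param type `"ranking"` (mean absolute attribution bars) or
#'   `"dependence"` (feature value vs attribution).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shapley_summary <- function(object, type = c("ranking", "dependence"), ...) {
  type <- match.arg(type)
  if (type == "ranking") {
    df <- object$ranking
    df$feature <- factor(df$feature, levels = rev(df$feature))
    ggplot(df, aes(x = .data$mean_abs_phi, y = .data$feature)) +
      geom_col() + theme_minimal() +
      labs(x = "mean |phi|", y = NULL, title = "Shapley feature importance")
  } else {
    ggplot(object$dependence, aes(x = .data$value, y = .data$phi)) +
      geom_point(alpha = 0.7) +
      ggplot2::facet_wrap(~feature, scales = "free_x") +
      theme_minimal() +
      labs(x = "feature value", y = "phi", title = "Shapley dependence")
  }
}

#' Plot a COP trajectory
#'
#' @param object A [cop_trajectory()].
#' @param ... Unused.
#' @return A ggplot statokinesigram (ML vs AP path).
#' @export
autoplot.cop_trajectory <- function(object, ...) {
  ggplot(as_tibble(object)[object$valid, ], aes(x = .data$ml, y = .data$ap)) +
    ggplot2::geom_path(alpha = 0.6) + coord_equal() + theme_minimal() +
    labs(x = "COP ML (mm)", y = "COP AP (mm)", title = "Statokinesigram")
}
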