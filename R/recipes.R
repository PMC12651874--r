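# The four analysis recipes: intervention clustering (PD pre/post),
# convergence towards healthy dynamics, SD-feature diagnosis, and
# pre-intervention heterogeneity. Each is a configured, seed-reproducible
# run of the full chain: features -> (selection) -> standardise -> t-SNE ->
# k-means -> validity indices -> descriptives -> effects/SHAP.

RECIPES <- list(
  intervention = list(perplexity = 2, k = c(3, 5), blocks = c("standing", "gait"),
    rows = "pd_both_sessions"),
  convergence = list(perplexity = 3, k = c(2, 3, 4), blocks = c("standing", "gait"),
    rows = "all"),
  diagnosis = list(perplexity = 3, k = 2, blocks = "signal_sd",
    rows = "pre_and_healthy"),
  baseline = list(perplexity = 1, k = 2, blocks = c("standing", "gait"),
    rows = "pd_pre")
)

# The default selected feature vector: the package's analogue of the
# selected triple (standing ML RMS, standing AP path length, gait-initiation
# loading-phase ML displacement).
DEFAULT_SFV <- c("rms_ml", "pl_ap", "ldisp")

recipe_rows <- function(table, rows) {
  switch(rows,
    all = rep(TRUE, nrow(table)),
    pd_both_sessions = table$group != "healthy",
    pd_pre = table$group != "healthy" & table$session == "pre",
    pre_and_healthy = table$session != "post",
    stopf("unknown row recipe '%s'", rows))
}

#' Subject plot labels
#'
#' Renders the cohort's plotting labels: subject id prefix (E =
#' intervention, C = PD control, H = healthy), `-A` for post-intervention
#' (after-exercise) sessions, then sex letter and age.
#'
#' @param table Tibble with `subject_id`, `session`, and optionally
#'   `sex`/`age` columns (numeric sex uses 0 = M, 1 = F).
#' @return Character vector of labels such as `"E01-A M47"`.
#' @export
subject_labels <- function(table) {
  sex <- if ("sex" %in% names(table)) table$sex else ""
  if (is.numeric(sex)) sex <- ifelse(sex > 0.5, "F", "M")
  age <- if ("age" %in% names(table)) table$age else ""
  paste0(table$subject_id,
    ifelse(table$session == "post", "-A", ""),
    " ", sex, age)
}

# Pre -> post cluster transitions per subject.
cluster_transitions <- function(table, labels) {
  df <- tibble(subject_id = table$subject_id, group = table$group,
    session = table$session, cluster = labels)
  wide <- df |>
    filter(.data$session %in% c("pre", "post")) |>
    tidyr::pivot_wider(names_from = "session", values_from = "cluster")
  wide$changed <- wide$pre != wide$post
  wide
}

#' Run an analysis recipe on a cohort
#'
#' @param cohort A [simulate_cohort()] or [read_cohort()] result.
#' @param recipe One of `"intervention"`, `"convergence"`, `"diagnosis"`,
#'   `"baseline"`.
#' @param seed Integer seed controlling embedding and clustering.
#' @param selection `"fixed"` uses the default selected feature vector
#'   (`rms_ml`, `pl_ap`, `ldisp`); `"ffs"` re-derives it by forward
#'   selection of PD vs healthy membership; `"all"` uses every feature of
#'   the recipe's blocks (always the case for the diagnosis recipe, which
#'   works on the channel-SD block).
#' @param k Cluster counts; defaults to the recipe's values.
#' @param perplexity t-SNE perplexity; defaults to the recipe's value.
#' @param bootstrap_B Bootstrap replicates for index CIs (0 skips).
#' @param n_init K-means restarts.
#' @param ... Passed to [cohort_feature_table()] (preprocessing options).
#' @return A `recipe_bundle` list: `recipe`, `feature_table` (standardised),
#'   `selected`, `embedding`, `kmeans` (named list per k), `indices`,
#'   `descriptives`, `transitions` (intervention-style recipes),
#'   `effects`, `shap`, `manifest`.
#' @export
run_recipe <- function(cohort, recipe = c("intervention", "convergence",
                                          "diagnosis", "baseline"),
                       seed = 42, selection = c("fixed", "ffs", "all"),
                       k = NULL, perplexity = NULL, bootstrap_B = 0,
                       n_init = 10, ...) {
  recipe <- match.arg(recipe)
  selection <- match.arg(selection)
  rc <- RECIPES[[recipe]]
  k <- k %||% rc$k
  perplexity <- perplexity %||% rc$perplexity

  table <- cohort_feature_table(cohort, blocks = rc$blocks,
    include_demographics = (recipe != "diagnosis"), ...)
  rows <- recipe_rows(table, rc$rows)

  selected <- feature_names(table)
  sel_result <- NULL
  if (recipe == "diagnosis" || selection == "all") {
    selected <- setdiff(selected, c("age", "sex", "bmi"))
  } else if (selection == "fixed") {
    selected <- intersect(DEFAULT_SFV, selected)
    if (length(selected) == 0) stopf("default feature vector absent from blocks")
  } else {
    pre_rows <- table$session != "post"
    labels <- as.integer(table$group[pre_rows] != "healthy")
    if (length(unique(labels)) < 2) {
      stopf("FFS needs both PD and healthy subjects in the cohort")
    }
    cand <- setdiff(feature_names(table), c("age", "sex", "bmi"))
    sel_result <- forward_select(table[pre_rows, cand], labels,
      classifier_spec("logistic_regression"), target_size = 3,
      seed = child_seed(seed, 101))
    selected <- sel_result$selected
  }

  sub <- table[rows, c(ID_COLS, selected)]
  attr(sub, "provenance") <- attr(table, "provenance")
  class(sub) <- class(table)
  std <- standardize_features(sub)
  X <- as.matrix(as.data.frame(std[, selected]))

  if (perplexity >= (nrow(X) - 1) / 3) {
    warn(sprintf("perplexity %g is large for n = %d points", perplexity, nrow(X)))
  }
  emb <- tsne(X, perplexity = perplexity, seed = child_seed(seed, 1))
  elbow <- elbow_curve(emb$Y, k_range = 1:min(8, nrow(X) - 1), n_init = n_init,
    seed = child_seed(seed, 2))

  km <- list(); idx <- list(); desc <- list(); trans <- list()
  for (kk in k) {
    fit <- kmeans_lloyd(emb$Y, kk, n_init = n_init, seed = child_seed(seed, 10 + kk))
    km[[as.character(kk)]] <- fit
    idx[[as.character(kk)]] <- if (kk >= 2) {
      bind_cols(tibble(k = kk), internal_indices(emb$Y, fit$labels))
    }
    desc[[as.character(kk)]] <- bind_cols(tibble(k = kk),
      cluster_descriptives(emb$Y, fit$labels))
    if (rc$rows %in% c("pd_both_sessions", "all")) {
      trans[[as.character(kk)]] <- cluster_transitions(std, fit$labels)
    }
  }
  boot <- NULL
  if (bootstrap_B > 0) {
    boot <- lapply(setNames(k[k >= 2], k[k >= 2]), function(kk) {
      bootstrap_indices(emb$Y, kk, B = bootstrap_B, seed = child_seed(seed, 20 + kk),
        n_init = n_init)
    })
  }

  effects <- NULL
  if (all(c("pre", "post") %in% std$session) && "pd_tpei" %in% std$group) {
    feats <- selected
    e_pre <- std$group == "pd_tpei" & std$session == "pre"
    e_post <- std$group == "pd_tpei" & std$session == "post"
    c_pre <- std$group == "pd_control" & std$session == "pre"
    c_post <- std$group == "pd_control" & std$session == "post"
    h <- std$group == "healthy"
    effects <- bind_rows(
      bind_cols(tibble(contrast = "tpei_pre_vs_post"),
        effect_size_table(std, e_pre, e_post, feats)),
      bind_cols(tibble(contrast = "control_pre_vs_post"),
        effect_size_table(std, c_pre, c_post, feats)),
      if (any(h)) bind_cols(tibble(contrast = "healthy_vs_tpei_post"),
        effect_size_table(std, h, e_post, feats)))
  }

  shap <- NULL
  if ("healthy" %in% std$group && length(selected) <= 12) {
    labels <- as.integer(std$group != "healthy")
    if (length(unique(labels)) == 2) {
      shap <- shap_logistic(std[, selected], labels, selected)
    }
  }

  manifest <- list(
    recipe = recipe, seed = seed, selection = selection,
    perplexity = perplexity, k = k, n_init = n_init,
    bootstrap_B = bootstrap_B, n_rows = nrow(std),
    selected = selected,
    config_hash = rlang::hash(list(recipe, seed, selection, perplexity, k,
      n_init, bootstrap_B, selected)),
    version = as.character(utils::packageVersion("swayshift")),
    defaults = list(fz_threshold = 50, cutoff_hz = 10, filter_order = 4,
      trim_standing_s = 2, trim_gait_precue_s = 1)
  )
  structure(list(
    recipe = recipe, feature_table = std, selected = selected,
    selection_result = sel_result, embedding = emb, elbow = elbow,
    kmeans = km, indices = bind_rows(idx), descriptives = bind_rows(desc),
    bootstrap = boot, transitions = trans, effects = effects, shap = shap,
    labels = subject_labels(std), manifest = manifest
  ), class = "recipe_bundle")
}

#' @export
print.recipe_bundle <- function(x, ...) {
  cat(sprintf("<recipe_bundle> '%s' on %d rows; features: %s\n",
    x$recipe, nrow(x$feature_table), paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Render a human-readable recipe report
#'
#' @param bundle A [run_recipe()] result.
#' @return A single markdown string (also classed `"recipe_report"` so it
#'   prints verbatim).
#' @export
report <- function(bundle) {
  stopifnot(inherits(bundle, "recipe_bundle"))
  fmt_tab <- function(df) {
    if (is.null(df) || nrow(df) == 0) return("(none)")
    paste(utils::capture.output(print(as.data.frame(df), digits = 4, row.names = FALSE)),
      collapse = "\n")
  }
  parts <- c(
    sprintf("# Recipe report: %s", bundle$recipe),
    sprintf("manifest hash: %s | seed %d | perplexity %g | k = %s",
      bundle$manifest$config_hash, bundle$manifest$seed,
      bundle$manifest$perplexity, paste(bundle$manifest$k, collapse = ",")),
    sprintf("\n## Features\n%s", paste(bundle$selected, collapse = ", ")),
    sprintf("\n## Cluster validity indices\n%s",
      if (is.null(bundle$indices) || nrow(bundle$indices) == 0) {
        "indices undefined (single cluster)"
      } else fmt_tab(bundle$indices)),
    sprintf("\n## Cluster descriptives\n%s", fmt_tab(bundle$descriptives))
  )
  if (!is.null(bundle$effects)) {
    parts <- c(parts, sprintf("\n## Effect sizes (Cohen's d)\n%s", fmt_tab(bundle$effects)))
  }
  if (!is.null(bundle$shap)) {
    parts <- c(parts, sprintf("\n## Shapley feature ranking\n%s",
      fmt_tab(bundle$shap$ranking)))
  }
  if (length(bundle$transitions) > 0) {
    tr <- bundle$transitions[[length(bundle$transitions)]]
    parts <- c(parts, sprintf("\n## Pre/post cluster transitions (k = %s)\n%s",
      names(bundle$transitions)[length(bundle$transitions)], fmt_tab(tr)))
  }
  structure(paste(parts, collapse = "\n"), class = "recipe_report")
}

#' @export
print.recipe_report <- function(x, ...) {
  cat(x, "\n")
  invisible(x)
}
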