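# Assembly of the subject-session feature matrix and its standardisation.

ID_COLS <- c("subject_id", "group", "session")

#' Assemble the subject-session feature table
#'
#' Joins named feature blocks (each a tibble keyed by `subject_id` and
#' `session`) and the demographics table into one row per subject-session.
#' Sex is encoded numerically (`M` = 0, `F` = 1). Column provenance (which
#' block each feature came from) is kept in the `"provenance"` attribute.
#'
#' @param blocks Named list of block tibbles; each must have `subject_id`
#'   and `session` columns plus numeric feature columns.
#' @param demographics Tibble with `subject_id`, `group`, `session`, `age`,
#'   `sex`, `bmi` (one row per subject-session).
#' @param include_demographics Add `age`, `sex`, `bmi` as features?
#' @return A `feature_table` tibble: id columns `subject_id`, `group`,
#'   `session`, then numeric feature columns. Attribute `standardized` is
#'   `FALSE`.
#' @export
build_feature_table <- function(blocks, demographics,
                                include_demographics = TRUE) {
  if (is.null(names(blocks)) || any(names(blocks) == "")) {
    stopf("`blocks` must be a named list")
  }
  key <- demographics[, intersect(c(ID_COLS, "age", "sex", "bmi"), names(demographics))]
  if (anyDuplicated(paste(key$subject_id, key$session))) {
    stopf("duplicate subject-session key in demographics")
  }
  tab <- key
  provenance <- list()
  for (nm in names(blocks)) {
    blk <- blocks[[nm]]
    if (!all(c("subject_id", "session") %in% names(blk))) {
      stopf("block '%s' lacks subject_id/session key columns", nm)
    }
    if (anyDuplicated(paste(blk$subject_id, blk$session))) {
      stopf("duplicate subject-session key in block '%s'", nm)
    }
    feat_cols <- setdiff(names(blk), c(ID_COLS, "age", "sex", "bmi"))
    provenance[nm] <- list(feat_cols)
    tab <- left_join(tab, blk[, c("subject_id", "session", feat_cols)],
      by = c("subject_id", "session"))
    miss <- !complete.cases(tab[, feat_cols])
    if (any(miss)) {
      stopf("record %s/%s is missing block '%s'",
        tab$subject_id[which(miss)[1]], tab$session[which(miss)[1]], nm)
    }
  }
  if (include_demographics && all(c("age", "sex", "bmi") %in% names(tab))) {
    tab$sex <- ifelse(tab$sex == "F", 1, 0)
    provenance$demographics <- c("age", "sex", "bmi")
  } else {
    tab$age <- NULL; tab$sex <- NULL; tab$bmi <- NULL
  }
  ids <- intersect(ID_COLS, names(tab))
  tab <- tab[, c(ids, setdiff(names(tab), ids))]
  structure(as_tibble(tab),
    provenance = provenance, standardized = FALSE,
    class = c("feature_table", class(tibble())))
}

#' Feature column names of a feature table
#' @param table A feature table.
#' @return Character vector of feature (non-id) column names.
#' @export
feature_names <- function(table) {
  setdiff(names(table), ID_COLS)
}

#' Standardise a feature table
#'
#' Column-wise z-scoring over all included rows (pre and post sessions are
#' scaled jointly, since downstream analyses embed them in one space).
#' Idempotent; the original means and SDs are kept in the `"scaling"`
#' attribute for the inverse transform.
#'
#' @param table A [build_feature_table()] result.
#' @return The standardised `feature_table` (attribute `standardized = TRUE`).
#' @export
standardize_features <- function(table) {
  feats <- feature_names(table)
  if (nrow(table) < 2) stopf("standardisation needs >= 2 rows")
  mu <- vapply(table[feats], mean, numeric(1))
  sg <- vapply(table[feats], sd, numeric(1))
  zero <- names(sg)[sg == 0]
  if (length(zero) > 0) {
    stopf("zero-variance column(s): %s", paste(zero, collapse = ", "))
  }
  out <- table
  for (f in feats) out[[f]] <- (out[[f]] - mu[[f]]) / sg[[f]]
  attr(out, "scaling") <- list(mean = mu, sd = sg)
  attr(out, "standardized") <- TRUE
  out
}

#' Extract features for a whole cohort
#'
#' Runs the preprocessing chain on every trial of a cohort and computes the
#' configured feature blocks: `standing` (posturography features of the
#' standing trial), `gait` (loading/unloading displacement and velocity),
#' and `signal_sd` (per-channel SDs of the standing trial).
#'
#' @param cohort A [simulate_cohort()] or [read_cohort()] result.
#' @param blocks Character subset of `c("standing", "gait", "signal_sd")`.
#' @param include_demographics Include `age`, `sex`, `bmi` columns?
#' @param ... Passed to [preprocess_trial()].
#' @return An unstandardised `feature_table`.
#' @export
cohort_feature_table <- function(cohort,
                                 blocks = c("standing", "gait", "signal_sd"),
                                 include_demographics = TRUE, ...) {
  blocks <- match.arg(blocks, several.ok = TRUE)
  standing_rows <- list(); gait_rows <- list(); sd_rows <- list()
  for (tr in cohort$trials) {
    m <- trial_meta(tr)
    key <- tibble(subject_id = m$subject_id, session = m$session)
    if (identical(m$test_type, "standing")) {
      cop <- preprocess_trial(tr, ...)
      if ("standing" %in% blocks) {
        standing_rows[[length(standing_rows) + 1L]] <-
          bind_cols(key, standing_features(cop))
      }
      if ("signal_sd" %in% blocks) {
        sd_rows[[length(sd_rows) + 1L]] <-
          bind_cols(key, signal_sd_features(tr, cop))
      }
    } else if (identical(m$test_type, "gait_initiation") && "gait" %in% blocks) {
      cop <- preprocess_trial(tr, ...)
      phases <- segment_gait_initiation(cop)
      gait_rows[[length(gait_rows) + 1L]] <- bind_cols(key, gait_features(cop, phases))
    }
  }
  blk <- list()
  if ("standing" %in% blocks) blk$standing <- bind_rows(standing_rows)
  if ("gait" %in% blocks) blk$gait <- bind_rows(gait_rows)
  if ("signal_sd" %in% blocks) blk$signal_sd <- bind_rows(sd_rows)
  build_feature_table(blk, cohort$profiles,
    include_demographics = include_demographics)
}

#' Write a feature table with its provenance sidecar
#'
#' @param table A `feature_table`.
#' @param path CSV output path; a JSON sidecar (`<path>.json`) records the
#'   column provenance and, if standardised, the scaling parameters.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  side <- list(
    provenance = attr(table, "provenance"),
    standardized = isTRUE(attr(table, "standardized")),
    scaling = attr(table, "scaling")
  )
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}
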