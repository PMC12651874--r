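# Trial serialisation in the plain-text ingest dialect:
# header `time,Fx,Fy,Fz,Mx,My,Mz`, comma separated, SI units.

#' Read a force-plate trial from CSV
#'
#' @param path Path to a trial CSV with header `time,Fx,Fy,Fz,Mx,My,Mz`.
#' @param meta Optional metadata list (e.g. one row of the cohort metadata
#'   table coerced to a list) attached to the trial.
#' @param fs Sampling rate; inferred from the time column when `NULL`.
#' @return A [forceplate_trial()].
#' @export
read_trial <- function(path, meta = list(), fs = NULL) {
  if (!file.exists(path)) stopf("no such trial file: %s", path)
  df <- read.csv(path, check.names = FALSE)
  needed <- c("time", CHANNELS)
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stopf("%s: missing channel column(s): %s", path, paste(missing, collapse = ", "))
  }
  bad <- which(!complete.cases(df[, needed]))
  if (length(bad) > 0) {
    stopf("%s: malformed rows (missing values) at data line(s): %s", path,
      paste(head(bad, 10), collapse = ", "))
  }
  if (is.null(fs)) {
    if (nrow(df) < 2) stopf("%s: cannot infer sampling rate from < 2 samples", path)
    fs <- 1 / median(diff(df$time))
  }
  forceplate_trial(df, fs = fs, meta = meta)
}

#' Write a force-plate trial to CSV
#'
#' @param trial A [forceplate_trial()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trial <- function(trial, path) {
  df <- as.data.frame(trial)[, c("time", CHANNELS)]
  write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing trial CSVs and `metadata.csv`.
#' @return A list with `trials` and `profiles`, shaped like a
#'   [simulate_cohort()] result (without `truth`).
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) stopf("no metadata.csv in %s", dir)
  profiles <- as_tibble(read.csv(meta_path))
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  files <- files[basename(files) != "metadata.csv"]
  trials <- list()
  for (f in files) {
    nm <- sub("\\.csv$", "", basename(f))
    parts <- strsplit(nm, "_")[[1]]
    if (length(parts) < 3) stopf("trial file name '%s' not in <id>_<session>_<test> form", nm)
    sid <- parts[1]; sess <- parts[2]; tt <- paste(parts[-(1:2)], collapse = "_")
    row <- profiles[profiles$subject_id == sid & profiles$session == sess, ]
    if (nrow(row) != 1) stopf("metadata row not found for %s/%s", sid, sess)
    m <- c(as.list(row), list(test_type = tt, events = list()))
    trials[[nm]] <- read_trial(f, meta = m)
  }
  list(trials = trials, profiles = profiles)
}
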