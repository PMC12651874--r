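# The force-plate trial container: a tibble of the six raw channels plus
# time, carrying the sampling rate and subject metadata as attributes.

CHANNELS <- c("Fx", "Fy", "Fz", "Mx", "My", "Mz")

#' Construct a force-plate trial
#'
#' A trial is a tibble with columns `time`, `Fx`, `Fy`, `Fz` (N) and
#' `Mx`, `My`, `Mz` (N m), a sampling rate attribute `fs` (Hz) and a
#' metadata list attribute `meta` (subject id, group, session, test type,
#' body mass, and named event times such as the gait-initiation cue).
#'
#' @param data Data frame with columns `time` plus the six channels.
#' @param fs Sampling rate in Hz.
#' @param meta Named list of metadata; free-form, but `subject_id`, `group`,
#'   `session`, `test_type` and `events` are used downstream.
#' @return A `forceplate_trial` tibble.
#' @export
forceplate_trial <- function(data, fs, meta = list()) {
  data <- as_tibble(data)
  needed <- c("time", CHANNELS)
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    stopf("trial is missing channel column(s): %s", paste(missing, collapse = ", "))
  }
  check_number(fs, "fs", positive = TRUE)
  dt <- diff(data$time)
  if (nrow(data) > 1) {
    if (any(dt <= 0)) stopf("`time` must be strictly increasing")
    if (max(abs(dt - 1 / fs)) > 1e-9) {
      stopf("non-uniform time step: max deviation %g s exceeds 1e-9 s", max(abs(dt - 1 / fs)))
    }
  }
  structure(data[, needed],
    fs = fs, meta = meta,
    class = c("forceplate_trial", class(tibble())))
}

#' @export
print.forceplate_trial <- function(x, ...) {
  m <- trial_meta(x)
  cat(sprintf(
    "<forceplate_trial> %s samples @ %g Hz | %s %s %s\n",
    format(nrow(x), big.mark = ","), trial_fs(x),
    m$subject_id %||% "?", m$test_type %||% "?", m$session %||% ""))
  NextMethod()
}

#' Sampling rate and metadata accessors
#' @param trial A `forceplate_trial`.
#' @return `trial_fs()` the sampling rate in Hz; `trial_meta()` the metadata list.
#' @export
trial_fs <- function(trial) attr(trial, "fs")

#' @rdname trial_fs
#' @export
trial_meta <- function(trial) attr(trial, "meta")
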