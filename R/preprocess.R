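# COP derivation, transient trimming, and zero-phase low-pass filtering.

#' Construct a COP trajectory
#'
#' A tibble with columns `time` (s), `ml`, `ap` (mm) and `valid` (logical),
#' carrying the sampling rate and inherited trial metadata as attributes.
#'
#' @param time,ml,ap,valid Equal-length vectors.
#' @param fs Sampling rate (Hz).
#' @param meta Metadata list inherited from the source trial.
#' @return A `cop_trajectory` tibble.
#' @export
cop_trajectory <- function(time, ml, ap, valid = rep(TRUE, length(ml)),
                           fs, meta = list()) {
  stopifnot(length(ml) == length(ap), length(ml) == length(time),
    length(valid) == length(ml))
  check_number(fs, "fs", positive = TRUE)
  structure(tibble(time = time, ml = ml, ap = ap, valid = valid),
    fs = fs, meta = meta,
    class = c("cop_trajectory", class(tibble())))
}

#' @export
print.cop_trajectory <- function(x, ...) {
  cat(sprintf("<cop_trajectory> %s samples @ %g Hz (%d valid)\n",
    format(nrow(x), big.mark = ","), attr(x, "fs"), sum(x$valid)))
  NextMethod()
}

#' Derive the COP trajectory from plate forces and moments
#'
#' With moments taken about the plate surface (vertical offset `z0`), the
#' centre of pressure is `COP_ML = (-My - Fx * z0) / Fz` and
#' `COP_AP = (Mx - Fy * z0) / Fz` (metres, converted to mm). Samples with
#' `Fz` below `fz_threshold` are marked invalid: the ratio is numerically
#' meaningless on an unloaded plate.
#'
#' @param trial A [forceplate_trial()].
#' @param fz_threshold Minimum vertical load (N) for a sample to be valid.
#' @param z0 Height of the plate surface above the moment reference plane (m).
#' @return A [cop_trajectory()] in mm.
#' @export
compute_cop <- function(trial, fz_threshold = 50, z0 = 0) {
  check_number(fz_threshold, "fz_threshold", positive = TRUE)
  valid <- trial$Fz >= fz_threshold
  if (!any(valid)) stopf("no loaded samples: Fz never reaches %g N", fz_threshold)
  fz <- ifelse(valid, trial$Fz, NA_real_)
  ml <- 1000 * (-trial$My - trial$Fx * z0) / fz
  ap <- 1000 * (trial$Mx - trial$Fy * z0) / fz
  cop_trajectory(trial$time, ml, ap, valid,
    fs = trial_fs(trial), meta = trial_meta(trial))
}

#' Trim transient head and tail from a COP trajectory
#'
#' @param cop A [cop_trajectory()].
#' @param head,tail Seconds removed from the start and end.
#' @return The trimmed [cop_trajectory()].
#' @export
trim_cop <- function(cop, head = 2, tail = 2) {
  check_number(head, "head", non_negative = TRUE)
  check_number(tail, "tail", non_negative = TRUE)
  fs <- attr(cop, "fs")
  n <- nrow(cop)
  n_head <- round(head * fs)
  n_tail <- round(tail * fs)
  if (n_head + n_tail >= n) {
    stopf("over-trim: removing %g + %g s leaves no samples of a %g s trajectory",
      head, tail, n / fs)
  }
  idx <- seq.int(n_head + 1L, n - n_tail)
  cop_trajectory(cop$time[idx], cop$ml[idx], cop$ap[idx], cop$valid[idx],
    fs = fs, meta = attr(cop, "meta"))
}

# Zero-phase Butterworth low-pass of one series. signal::filtfilt applies
# the filter forward and backward but starts from zero state, so we demean,
# pad by odd reflection (scipy-style), filter, unpad and restore the mean.
# DC is preserved exactly by the demean/restore step.
zero_phase_lowpass <- function(x, fs, cutoff, order) {
  n <- length(x)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  mu <- mean(x)
  xc <- x - mu
  padlen <- min(n - 1L, max(3L * (order + 1L), ceiling(2 * fs / cutoff)))
  pre <- 2 * xc[1] - xc[seq.int(padlen + 1L, 2L)]
  post <- 2 * xc[n] - xc[seq.int(n - 1L, n - padlen)]
  y <- signal::filtfilt(bf, c(pre, xc, post))
  y[seq.int(padlen + 1L, padlen + n)] + mu
}

#' Zero-phase low-pass filter a COP trajectory
#'
#' Forward-backward (zero-phase) Butterworth filtering per axis. Length and
#' DC level are preserved; the effective magnitude response is the squared
#' single-pass response.
#'
#' @param cop A [cop_trajectory()].
#' @param cutoff Cut-off frequency (Hz); must lie below the Nyquist rate.
#' @param order Butterworth order of the single pass; >= 1.
#' @return The filtered [cop_trajectory()].
#' @export
lowpass_cop <- function(cop, cutoff = 10, order = 4) {
  fs <- attr(cop, "fs")
  check_number(cutoff, "cutoff", positive = TRUE)
  if (cutoff >= fs / 2) {
    stopf("cutoff %g Hz must be below the Nyquist frequency %g Hz", cutoff, fs / 2)
  }
  if (order < 1) stopf("`order` must be >= 1")
  cop_trajectory(cop$time,
    zero_phase_lowpass(cop$ml, fs, cutoff, order),
    zero_phase_lowpass(cop$ap, fs, cutoff, order),
    cop$valid, fs = fs, meta = attr(cop, "meta"))
}

#' Standard preprocessing chain for one trial
#'
#' COP derivation, transient trimming and zero-phase low-pass filtering.
#' Standing trials are trimmed symmetrically (`head = tail = trim_standing`);
#' gait-initiation trials keep everything from `trim_gait_precue` seconds
#' before the cue onwards, so the movement and follow-through are retained.
#'
#' @param trial A [forceplate_trial()].
#' @param fz_threshold,z0 See [compute_cop()].
#' @param trim_standing Head/tail trim for standing trials (s).
#' @param trim_gait_precue Pre-cue head retained for gait trials (s).
#' @param cutoff,order See [lowpass_cop()].
#' @return A preprocessed [cop_trajectory()].
#' @export
preprocess_trial <- function(trial, fz_threshold = 50, z0 = 0,
                             trim_standing = 2, trim_gait_precue = 1,
                             cutoff = 10, order = 4) {
  cop <- compute_cop(trial, fz_threshold = fz_threshold, z0 = z0)
  meta <- trial_meta(trial)
  if (identical(meta$test_type, "gait_initiation")) {
    cue <- meta$events$cue %||% 3
    head <- max(0, cue - trim_gait_precue)
    cop <- trim_cop(cop, head = head, tail = 0)
  } else {
    cop <- trim_cop(cop, head = trim_standing, tail = trim_standing)
  }
  lowpass_cop(cop, cutoff = cutoff, order = order)
}

#' Write a preprocessed COP trajectory to CSV
#'
#' Columns `time,cop_ml_mm,cop_ap_mm,valid`.
#'
#' @param cop A [cop_trajectory()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cop <- function(cop, path) {
  df <- data.frame(time = cop$time, cop_ml_mm = cop$ml,
    cop_ap_mm = cop$ap, valid = cop$valid)
  write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
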