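# Mechanics-informed feature extraction from COP trajectories and raw
# channels: quiet-standing posturography, gait-initiation phase features,
# and per-channel variability.

#' Quiet-standing posturography features
#'
#' Computes, over the valid samples of a preprocessed trajectory:
#' per-axis and planar path length (sum of absolute / Euclidean increments,
#' mm), RMS and variance of the demeaned COP (mm, mm^2), mean sway
#' velocity (path length / duration, mm/s), and sway area as the 95%
#' prediction-ellipse area `pi * chi2_2(0.95) * sqrt(det(cov))` (mm^2).
#'
#' @param cop A [cop_trajectory()].
#' @return One-row tibble with columns `pl_ml`, `pl_ap`, `pl_total`,
#'   `rms_ml`, `rms_ap`, `var_ml`, `var_ap`, `vmean_ml`, `vmean_ap`,
#'   `vmean_total`, `sway_area`.
#' @export
standing_features <- function(cop) {
  ml <- cop$ml[cop$valid]
  ap <- cop$ap[cop$valid]
  n <- length(ml)
  if (n < 2) stopf("standing features need >= 2 valid samples (got %d)", n)
  fs <- attr(cop, "fs")
  duration <- (n - 1) / fs
  dml <- diff(ml)
  dap <- diff(ap)
  pl_ml <- sum(abs(dml))
  pl_ap <- sum(abs(dap))
  pl_total <- sum(sqrt(dml^2 + dap^2))
  mlc <- ml - mean(ml)
  apc <- ap - mean(ap)
  rms_ml <- sqrt(mean(mlc^2))
  rms_ap <- sqrt(mean(apc^2))
  cv <- cov(cbind(mlc, apc))
  det_cv <- max(0, cv[1, 1] * cv[2, 2] - cv[1, 2]^2)
  tibble(
    pl_ml = pl_ml, pl_ap = pl_ap, pl_total = pl_total,
    rms_ml = rms_ml, rms_ap = rms_ap,
    var_ml = rms_ml^2, var_ap = rms_ap^2,
    vmean_ml = pl_ml / duration, vmean_ap = pl_ap / duration,
    vmean_total = pl_total / duration,
    sway_area = pi * qchisq(0.95, df = 2) * sqrt(det_cv)
  )
}

#' Segment a gait-initiation trajectory into loading and unloading phases
#'
#' Onset is the first post-cue time at which the planar COP deviation from
#' the pre-cue baseline mean exceeds `k_threshold` baseline standard
#' deviations, sustained for at least `min_sustain` seconds. The loading
#' phase ends at the first mediolateral extremum after onset (the swing-limb
#' direction is auto-detected from the dominant early ML excursion); the
#' unloading phase ends at the subsequent recrossing of the baseline ML
#' level, or at the end of the trajectory.
#'
#' @param cop A [cop_trajectory()] covering the cue and the movement.
#' @param cue_time Cue time (s); taken from trial metadata when `NULL`.
#' @param baseline_window Pre-cue window used for the baseline statistics (s).
#' @param k_threshold Onset threshold in baseline SD units.
#' @param min_sustain Minimum supra-threshold duration for onset (s).
#' @return A `gait_phases` list: `onset`, `loading_end`, `unloading_end`
#'   (s, on the trajectory's time axis) plus detection diagnostics
#'   (`baseline_ml`, `baseline_ap`, `baseline_sd`, `threshold`).
#' @export
segment_gait_initiation <- function(cop, cue_time = NULL, baseline_window = 2,
                                    k_threshold = 3, min_sustain = 0.05) {
  meta <- attr(cop, "meta")
  if (is.null(cue_time)) cue_time <- meta$events$cue
  if (is.null(cue_time)) stopf("`cue_time` is neither given nor in metadata")
  fs <- attr(cop, "fs")
  t <- cop$time
  base_idx <- which(t >= cue_time - baseline_window & t < cue_time)
  if (length(base_idx) < 2) stopf("baseline window holds < 2 samples before the cue")
  b_ml <- mean(cop$ml[base_idx])
  b_ap <- mean(cop$ap[base_idx])
  dev_base <- sqrt((cop$ml[base_idx] - b_ml)^2 + (cop$ap[base_idx] - b_ap)^2)
  b_sd <- max(sd(dev_base), 1e-9)
  threshold <- k_threshold * b_sd

  post <- which(t >= cue_time)
  dev <- sqrt((cop$ml[post] - b_ml)^2 + (cop$ap[post] - b_ap)^2)
  need <- max(1L, round(min_sustain * fs))
  above <- dev > threshold
  run <- rle(above)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  hit <- which(run$values & run$lengths >= need)
  if (length(hit) == 0) stopf("no initiation detected after the cue")
  onset_idx <- post[starts[hit[1]]]
  onset <- t[onset_idx]

  # swing-limb direction: sign of the first substantial ML excursion after
  # onset (a quarter of the maximum absolute excursion, at least the onset
  # threshold) - the later reversal towards the stance side is larger in
  # duration, so a global argmax would misread the direction
  ml0 <- cop$ml - b_ml
  horizon <- min(nrow(cop), onset_idx + round(2 * fs))
  seg <- seq.int(onset_idx, horizon)
  dir_thr <- max(threshold, 0.25 * max(abs(ml0[seg])))
  first_exc <- seg[abs(ml0[seg]) >= dir_thr]
  dir <- if (length(first_exc) > 0) sign(ml0[first_exc[1]]) else
    sign(ml0[seg][which.max(abs(ml0[seg]))])
  if (dir == 0) dir <- 1
  m <- dir * ml0

  # loading ends at the ML extremum in the swing direction: the maximum of
  # the oriented excursion between onset and its first recrossing of the
  # baseline level (robust to filter ripple near the onset)
  exceeded <- seg[m[seg] > threshold]
  search_end <- horizon
  if (length(exceeded) > 0) {
    after_exceed <- seq.int(exceeded[1], nrow(cop))
    recross <- after_exceed[m[after_exceed] <= 0]
    if (length(recross) > 0) search_end <- recross[1]
  }
  window <- seq.int(onset_idx, max(search_end, onset_idx + 1L))
  peak_idx <- window[which.max(m[window])]
  if (peak_idx <= onset_idx) peak_idx <- onset_idx + 1L
  loading_end <- t[peak_idx]

  after <- seq.int(peak_idx, nrow(cop))
  cross_rel <- which(m[after] <= 0)
  unloading_end <- if (length(cross_rel) == 0) t[nrow(cop)] else t[after[cross_rel[1]]]

  structure(list(
    onset = onset, loading_end = loading_end, unloading_end = unloading_end,
    swing_direction = dir,
    baseline_ml = b_ml, baseline_ap = b_ap,
    baseline_sd = b_sd, threshold = threshold, cue_time = cue_time
  ), class = "gait_phases")
}

#' Gait-initiation displacement and velocity features
#'
#' Per phase (loading, unloading) and axis (ML, AP): net displacement
#' magnitude `|COP(end) - COP(start)|` (mm) and mean velocity
#' (net displacement / phase duration, mm/s). `ldisp` is the loading-phase
#' ML displacement - the anticipatory postural adjustment amplitude.
#'
#' @param cop A [cop_trajectory()].
#' @param phases A [segment_gait_initiation()] result.
#' @return One-row tibble with columns `ldisp`, `ldisp_ap`, `udisp_ml`,
#'   `udisp_ap`, `lvel_ml`, `lvel_ap`, `uvel_ml`, `uvel_ap`.
#' @export
gait_features <- function(cop, phases) {
  t <- cop$time
  at <- function(tt) {
    i <- which.min(abs(t - tt))
    c(ml = cop$ml[i], ap = cop$ap[i])
  }
  span <- function(t0, t1, prefix_d, prefix_v) {
    dur <- t1 - t0
    if (dur <= 0) stopf("zero-length phase [%g, %g]", t0, t1)
    a <- at(t0); b <- at(t1)
    d <- abs(b - a)
    out <- c(d, d / dur)
    names(out) <- c(paste0(prefix_d, c("_ml", "_ap")), paste0(prefix_v, c("_ml", "_ap")))
    out
  }
  l <- span(phases$onset, phases$loading_end, "ldisp", "lvel")
  u <- span(phases$loading_end, phases$unloading_end, "udisp", "uvel")
  tibble(
    ldisp = unname(l["ldisp_ml"]), ldisp_ap = unname(l["ldisp_ap"]),
    udisp_ml = unname(u["udisp_ml"]), udisp_ap = unname(u["udisp_ap"]),
    lvel_ml = unname(l["lvel_ml"]), lvel_ap = unname(l["lvel_ap"]),
    uvel_ml = unname(u["uvel_ml"]), uvel_ap = unname(u["uvel_ap"])
  )
}

#' Per-channel variability features
#'
#' Sample standard deviation (n - 1 denominator) of each raw channel and of
#' the two COP axes over the (trimmed) trial.
#'
#' @param trial A [forceplate_trial()].
#' @param cop A [cop_trajectory()] derived from the trial.
#' @return One-row tibble with columns `sd_fx` ... `sd_mz`, `sd_cop_ml`,
#'   `sd_cop_ap`.
#' @export
signal_sd_features <- function(trial, cop) {
  if (nrow(trial) < 2) stopf("signal SD features need >= 2 samples")
  out <- as.list(vapply(CHANNELS, function(ch) sd(trial[[ch]]), numeric(1)))
  names(out) <- paste0("sd_", tolower(CHANNELS))
  out$sd_cop_ml <- sd(cop$ml[cop$valid])
  out$sd_cop_ap <- sd(cop$ap[cop$valid])
  as_tibble(out)
}
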