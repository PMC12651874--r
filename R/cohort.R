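# Cohort-level simulation: group presets, per-subject parameter jitter,
# intervention shift, and deterministic trial generation.

#' Group-level generative presets
#'
#' The `"study"` preset encodes the intended group contrasts: patients sway
#' with larger mediolateral amplitude and larger anterior-posterior drift
#' than healthy controls, and produce a smaller lateral anticipatory
#' excursion when initiating gait. The `"signal_recovery"` preset plants
#' group signal in the sway diffusion scales only (read through
#' mediolateral RMS and anterior-posterior path length), keeping gait and
#' demographics identical across groups; recovery tests exclude the
#' same-axis aliases of the planted pair from their candidate sets.
#'
#' @param variant `"study"` or `"signal_recovery"`.
#' @return Named list of per-group `list(sway, gait)` presets.
#' @export
group_presets <- function(variant = c("study", "signal_recovery")) {
  variant <- match.arg(variant)
  healthy <- list(
    sway = sway_params(theta_ml = 1, theta_ap = 1, sigma_ml = 1, sigma_ap = 1.2),
    gait = gait_params(apa_ml_amplitude = 30, apa_ap_amplitude = -40)
  )
  if (variant == "study") {
    # Contrast magnitudes are calibrated to the huge-effect regime reported
    # for the discriminating sway features in cohorts of this kind
    # (healthy-vs-patient Cohen's |d| of roughly 4-12), which dominates
    # anthropometric (mass) variation in the channel-SD features.
    pd_sway <- sway_params(theta_ml = 1, theta_ap = 1, sigma_ml = 8, sigma_ap = 5)
    pd_gait <- gait_params(apa_ml_amplitude = 18, apa_ap_amplitude = -24)
  } else {
    # Plant the contrasts through the diffusion scales at matched theta:
    # RMS and path length on an axis both scale with sigma, so the planted
    # pair is read through rms_ml and pl_ap while their same-axis aliases
    # (pl_ml, rms_ap) are excluded from candidate sets in recovery tests.
    # The 5x scale puts the raw-feature contrasts in the huge-effect
    # regime (Cohen's |d| ~ 3.5-4.5) reported for these features.
    pd_sway <- sway_params(theta_ml = 1, theta_ap = 1, sigma_ml = 5, sigma_ap = 6)
    pd_gait <- healthy$gait
  }
  list(
    healthy = healthy,
    pd_control = list(sway = pd_sway, gait = pd_gait),
    pd_tpei = list(sway = pd_sway, gait = pd_gait)
  )
}

# Demographic sampling models per group. The study variant mirrors the
# reference cohort summaries (PD groups older than healthy controls); the
# signal_recovery variant uses one shared model so demographics carry no
# group information.
group_demographics <- function(variant) {
  shared <- list(age_mean = 55, age_sd = 10, bmi_mean = 25, bmi_sd = 3, p_male = 0.6)
  if (variant == "signal_recovery") {
    return(list(healthy = shared, pd_control = shared, pd_tpei = shared))
  }
  list(
    healthy = list(age_mean = 23.7, age_sd = 1.4, bmi_mean = 23.8, bmi_sd = 3.3, p_male = 0.5),
    pd_control = list(age_mean = 68.2, age_sd = 9.1, bmi_mean = 25.5, bmi_sd = 1.4, p_male = 0.67),
    pd_tpei = list(age_mean = 50.8, age_sd = 14.4, bmi_mean = 24.2, bmi_sd = 5.7, p_male = 0.83)
  )
}

#' Cohort simulation configuration
#'
#' @param n_healthy,n_pd_control,n_pd_tpei Group sizes; all > 0.
#' @param variant Generative preset, see [group_presets()].
#' @param intervention_shift Convex shift of intervention-group (pd_tpei)
#'   post-session parameters towards the healthy preset: a parameter p
#'   becomes `(1 - lambda) * p + lambda * p_healthy` with
#'   `lambda = intervention_shift` in `[0, 1]`.
#' @param subject_cv Between-subject multiplicative coefficient of variation
#'   applied to sway scales, rates and APA amplitudes.
#' @param standing_duration,fs Standing-trial length (s) and sampling rate (Hz).
#' @param test_types Which tests to simulate per subject-session.
#' @param fz_noise_rel,fxy_noise_sd Channel noise settings, see
#'   [simulate_standing_trial()].
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_healthy = 6, n_pd_control = 6, n_pd_tpei = 6,
                          variant = c("study", "signal_recovery"),
                          intervention_shift = 0.6,
                          subject_cv = 0.2,
                          standing_duration = 30, fs = 1000,
                          test_types = c("standing", "gait_initiation"),
                          fz_noise_rel = 0.005, fxy_noise_sd = 2) {
  variant <- match.arg(variant)
  for (nm in c("n_healthy", "n_pd_control", "n_pd_tpei")) {
    n <- get(nm)
    if (!is.numeric(n) || n < 1) stopf("`%s` must be >= 1 (empty groups rejected)", nm)
  }
  if (intervention_shift < 0 || intervention_shift > 1) {
    stopf("`intervention_shift` must be in [0, 1]")
  }
  test_types <- match.arg(test_types, several.ok = TRUE)
  structure(list(
    n = c(healthy = n_healthy, pd_control = n_pd_control, pd_tpei = n_pd_tpei),
    variant = variant,
    presets = group_presets(variant),
    demographics = group_demographics(variant),
    intervention_shift = intervention_shift,
    subject_cv = subject_cv,
    standing_duration = standing_duration, fs = fs,
    test_types = test_types,
    fz_noise_rel = fz_noise_rel, fxy_noise_sd = fxy_noise_sd
  ), class = "cohort_config")
}

# Jitter a sway/gait preset multiplicatively for one subject.
jitter_params <- function(preset, cv) {
  sw <- preset$sway
  gp <- preset$gait
  j <- function(x) x * exp(rnorm(1, 0, cv))
  preset$sway <- sway_params(
    theta_ml = j(sw$theta_ml), theta_ap = j(sw$theta_ap),
    sigma_ml = j(sw$sigma_ml), sigma_ap = j(sw$sigma_ap),
    cop_offset_ml = sw$cop_offset_ml + rnorm(1, 0, 2),
    cop_offset_ap = sw$cop_offset_ap + rnorm(1, 0, 2)
  )
  preset$gait <- gait_params(
    cue_time = gp$cue_time,
    apa_ml_amplitude = j(gp$apa_ml_amplitude),
    apa_ap_amplitude = j(gp$apa_ap_amplitude),
    loading_duration = gp$loading_duration,
    unloading_duration = gp$unloading_duration,
    template_noise_sd = gp$template_noise_sd
  )
  preset
}

# Convex shift of subject parameters towards the healthy preset.
shift_towards_healthy <- function(params, healthy, lambda) {
  mix <- function(a, b) (1 - lambda) * a + lambda * b
  params$sway <- sway_params(
    theta_ml = mix(params$sway$theta_ml, healthy$sway$theta_ml),
    theta_ap = mix(params$sway$theta_ap, healthy$sway$theta_ap),
    sigma_ml = mix(params$sway$sigma_ml, healthy$sway$sigma_ml),
    sigma_ap = mix(params$sway$sigma_ap, healthy$sway$sigma_ap),
    cop_offset_ml = params$sway$cop_offset_ml,
    cop_offset_ap = params$sway$cop_offset_ap
  )
  params$gait <- gait_params(
    cue_time = params$gait$cue_time,
    apa_ml_amplitude = mix(params$gait$apa_ml_amplitude, healthy$gait$apa_ml_amplitude),
    apa_ap_amplitude = mix(params$gait$apa_ap_amplitude, healthy$gait$apa_ap_amplitude),
    loading_duration = params$gait$loading_duration,
    unloading_duration = params$gait$unloading_duration,
    template_noise_sd = params$gait$template_noise_sd
  )
  params
}

#' Simulate a full synthetic cohort
#'
#' Draws per-subject generative parameters around the group presets,
#' applies the intervention shift to post-session parameters of the
#' pd_tpei group, and simulates every configured trial. Deterministic:
#' identical `(config, seed)` yields identical output.
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed.
#' @return A `sway_cohort` list with elements `trials` (list of
#'   [forceplate_trial()]), `profiles` (tibble: one row per subject-session
#'   with demographics), and `truth` (tibble of true generative parameters
#'   per subject-session, for recovery tests).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  prefix <- c(healthy = "H", pd_control = "C", pd_tpei = "E")
  subjects <- with_seed(child_seed(seed, 0), {
    out <- list()
    for (grp in names(config$n)) {
      dm <- config$demographics[[grp]]
      for (i in seq_len(config$n[[grp]])) {
        id <- sprintf("%s%02d", prefix[[grp]], i)
        pars <- jitter_params(config$presets[[grp]], config$subject_cv)
        age <- round(max(20, min(85, rnorm(1, dm$age_mean, dm$age_sd))))
        bmi <- round(max(17, min(34, rnorm(1, dm$bmi_mean, dm$bmi_sd))), 1)
        height <- rnorm(1, 1.70, 0.07)
        out[[id]] <- list(
          id = id, group = grp, params = pars,
          age = age, sex = if (runif(1) < dm$p_male) "M" else "F",
          bmi = bmi, mass = round(bmi * height^2, 1)
        )
      }
    }
    out
  })

  trials <- list()
  profile_rows <- list()
  truth_rows <- list()
  trial_idx <- 0L
  for (sub in subjects) {
    sessions <- if (sub$group == "healthy") "single" else c("pre", "post")
    for (sess in sessions) {
      pars <- sub$params
      if (sub$group == "pd_tpei" && sess == "post") {
        pars <- shift_towards_healthy(pars, config$presets$healthy,
          config$intervention_shift)
      }
      prof <- subject_profile(sub$id, sub$group, sess,
        age = sub$age, sex = sub$sex, bmi = sub$bmi, mass = sub$mass,
        sway = pars$sway, gait = pars$gait)
      key <- paste(sub$id, sess, sep = "_")
      profile_rows[[key]] <- tibble(
        subject_id = sub$id, group = sub$group, session = sess,
        age = sub$age, sex = sub$sex, bmi = sub$bmi, mass = sub$mass)
      truth_rows[[key]] <- tibble(
        subject_id = sub$id, group = sub$group, session = sess,
        theta_ml = pars$sway$theta_ml, theta_ap = pars$sway$theta_ap,
        sigma_ml = pars$sway$sigma_ml, sigma_ap = pars$sway$sigma_ap,
        apa_ml_amplitude = pars$gait$apa_ml_amplitude,
        apa_ap_amplitude = pars$gait$apa_ap_amplitude)
      for (tt in config$test_types) {
        trial_idx <- trial_idx + 1L
        tseed <- child_seed(seed, trial_idx)
        tr <- if (tt == "standing") {
          simulate_standing_trial(prof,
            duration = config$standing_duration, fs = config$fs, seed = tseed,
            fz_noise_rel = config$fz_noise_rel, fxy_noise_sd = config$fxy_noise_sd)
        } else {
          simulate_gait_initiation_trial(prof, fs = config$fs, seed = tseed,
            fz_noise_rel = config$fz_noise_rel, fxy_noise_sd = config$fxy_noise_sd)
        }
        trials[[paste(key, tt, sep = "_")]] <- tr
      }
    }
  }
  structure(list(
    trials = trials,
    profiles = bind_rows(profile_rows),
    truth = bind_rows(truth_rows),
    config = config, seed = seed
  ), class = "sway_cohort")
}

#' @export
print.sway_cohort <- function(x, ...) {
  cat(sprintf("<sway_cohort> %d trials, %d subject-sessions (seed %d, variant '%s')\n",
    length(x$trials), nrow(x$profiles), x$seed, x$config$variant))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes one CSV per trial in the ingest dialect
#' (`time,Fx,Fy,Fz,Mx,My,Mz`, SI units), a `metadata.csv` sidecar table
#' (subject_id, group, session, age, sex, bmi, mass), and a `truth.json`
#' file with the generative parameters. Output is byte-identical across
#' runs for identical cohorts.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written trial file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(cohort$trials)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write_trial(cohort$trials[[nm]], p)
    paths <- c(paths, p)
  }
  write.csv(cohort$profiles, file.path(dir, "metadata.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
    digits = NA, dataframe = "rows")
  invisible(paths)
}
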