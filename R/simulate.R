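# Synthetic force-plate cohort generator.
#
# Standing sway is modelled as an independent mean-reverting
# (Ornstein-Uhlenbeck) diffusion per axis, discretised by Euler-Maruyama:
#   c[t+1] = c[t] + theta * (mu - c[t]) * dt + sigma * sqrt(dt) * eps.
# The process has closed-form stationary moments (sd = sigma / sqrt(2 theta)),
# which anchors the generator's correctness tests. Force and moment channels
# are reconstructed from the latent COP through the plate identity
# Mx = COP_AP * Fz, My = -COP_ML * Fz (COP in metres), so that downstream
# COP recovery is exact by construction.

#' Standing-sway generative parameters
#'
#' @param theta_ml,theta_ap Mean-reversion rate per axis (1/s); must be > 0.
#' @param sigma_ml,sigma_ap Diffusion scale per axis (mm/sqrt(s)); >= 0.
#' @param cop_offset_ml,cop_offset_ap Equilibrium COP position (mm).
#' @return A `sway_params` list.
#' @export
sway_params <- function(theta_ml = 1, theta_ap = 1,
                        sigma_ml = 1, sigma_ap = 1.2,
                        cop_offset_ml = 0, cop_offset_ap = 0) {
  check_number(theta_ml, "theta_ml", positive = TRUE)
  check_number(theta_ap, "theta_ap", positive = TRUE)
  check_number(sigma_ml, "sigma_ml", non_negative = TRUE)
  check_number(sigma_ap, "sigma_ap", non_negative = TRUE)
  structure(list(
    theta_ml = theta_ml, theta_ap = theta_ap,
    sigma_ml = sigma_ml, sigma_ap = sigma_ap,
    cop_offset_ml = cop_offset_ml, cop_offset_ap = cop_offset_ap
  ), class = "sway_params")
}

#' Gait-initiation COP template parameters
#'
#' The template holds the baseline COP for `cue_time` seconds, then performs a
#' single-step anticipatory postural adjustment: a half-cosine lateral (and
#' posterior) excursion of amplitude `apa_ml_amplitude` over
#' `loading_duration`, followed by a half-cosine reversal towards the stance
#' side over `unloading_duration`.
#'
#' @param cue_time Quiet-stance time before the verbal cue (s); >= 1.
#' @param apa_ml_amplitude Signed lateral APA amplitude towards the swing limb (mm).
#' @param apa_ap_amplitude Signed posterior APA amplitude (mm, negative = posterior).
#' @param loading_duration,unloading_duration Phase durations (s); > 0.
#' @param template_noise_sd Additive white noise on the latent COP (mm).
#' @return A `gait_params` list.
#' @export
gait_params <- function(cue_time = 3, apa_ml_amplitude = 30,
                        apa_ap_amplitude = -40,
                        loading_duration = 0.5, unloading_duration = 0.6,
                        template_noise_sd = 0.5) {
  check_number(cue_time, "cue_time")
  if (cue_time < 1) stopf("`cue_time` must be >= 1 s (got %g)", cue_time)
  check_number(loading_duration, "loading_duration", positive = TRUE)
  check_number(unloading_duration, "unloading_duration", positive = TRUE)
  check_number(template_noise_sd, "template_noise_sd", non_negative = TRUE)
  structure(list(
    cue_time = cue_time,
    apa_ml_amplitude = apa_ml_amplitude,
    apa_ap_amplitude = apa_ap_amplitude,
    loading_duration = loading_duration,
    unloading_duration = unloading_duration,
    template_noise_sd = template_noise_sd
  ), class = "gait_params")
}

#' Subject profile for simulation
#'
#' @param subject_id Subject identifier.
#' @param group One of `"healthy"`, `"pd_control"`, `"pd_tpei"`.
#' @param session One of `"pre"`, `"post"`, `"single"`; healthy subjects use
#'   `"single"`.
#' @param age Age in years.
#' @param sex `"M"` or `"F"`.
#' @param bmi Body mass index (kg/m^2).
#' @param mass Body mass (kg); > 0.
#' @param sway A [sway_params()] object.
#' @param gait A [gait_params()] object.
#' @return A `subject_profile` list.
#' @export
subject_profile <- function(subject_id, group, session = "single",
                            age = 60, sex = "M", bmi = 25, mass = 75,
                            sway = sway_params(), gait = gait_params()) {
  group <- match.arg(group, c("healthy", "pd_control", "pd_tpei"))
  session <- match.arg(session, c("pre", "post", "single"))
  if (group == "healthy" && session != "single") {
    stopf("healthy subjects have a single session (got session = '%s')", session)
  }
  if (group != "healthy" && session == "single") {
    stopf("PD subjects have 'pre'/'post' sessions (got 'single')")
  }
  check_number(mass, "mass", positive = TRUE)
  sex <- match.arg(sex, c("M", "F"))
  structure(list(
    subject_id = subject_id, group = group, session = session,
    age = age, sex = sex, bmi = bmi, mass = mass,
    sway = sway, gait = gait
  ), class = "subject_profile")
}

# Euler-Maruyama OU path, initialised at a stationary draw so the series has
# no burn-in transient. Returns a vector of length n.
ou_path <- function(n, theta, sigma, mu, dt) {
  if (sigma == 0) return(rep(mu, n))
  a <- 1 - theta * dt
  if (a <= -1) stopf("unstable discretisation: theta * dt = %g >= 2", theta * dt)
  c0 <- mu + sigma / sqrt(2 * theta) * rnorm(1)
  innov <- theta * mu * dt + sigma * sqrt(dt) * rnorm(n - 1)
  c(c0, stats::filter(innov, a, method = "recursive", init = c0) + 0)
}

# Build the six channels from a latent COP path (mm) for a subject of given
# mass. Vertical load carries multiplicative noise (default 0.5% of body
# weight); the moment channels satisfy the plate identity exactly. The
# horizontal shear channels are mechanically coupled to the sway: the centre
# of mass is approximated by the 1 Hz low-passed COP and Newton's second law
# gives Fx = mass * a_ml (plus sensor noise, default SD 2 N), so that the
# variability of every channel reflects the subject's sway dynamics as it
# does on a real plate.
channels_from_cop <- function(cop_ml, cop_ap, mass, fs,
                              fz_noise_rel = 0.005, fxy_noise_sd = 2,
                              mz_noise_sd = 0.5) {
  n <- length(cop_ml)
  fz <- mass * .G * (1 + fz_noise_rel * rnorm(n))
  # second derivative of the smoothed COP, in m/s^2
  com_accel <- function(x) {
    if (n < 5 || fs <= 4) return(numeric(n))
    com <- zero_phase_lowpass(x, fs, cutoff = 1, order = 2) / 1000
    a <- c(0, diff(com, differences = 2), 0) * fs^2
    a
  }
  tibble(
    Fx = mass * com_accel(cop_ml) + fxy_noise_sd * rnorm(n),
    Fy = mass * com_accel(cop_ap) + fxy_noise_sd * rnorm(n),
    Fz = fz,
    Mx = (cop_ap / 1000) * fz,
    My = -(cop_ml / 1000) * fz,
    Mz = mz_noise_sd * rnorm(n)
  )
}

#' Simulate a quiet-standing force-plate trial
#'
#' @param profile A [subject_profile()].
#' @param duration Trial duration (s); > 0.
#' @param fs Sampling rate (Hz); > 0.
#' @param seed Integer seed; the trial is a pure function of
#'   (profile, duration, fs, seed).
#' @param fz_noise_rel Multiplicative Fz noise relative to body weight.
#' @param fxy_noise_sd Shear-force noise SD (N).
#' @return A [forceplate_trial()] with `test_type = "standing"`.
#' @export
simulate_standing_trial <- function(profile, duration = 30, fs = 1000, seed = 1,
                                    fz_noise_rel = 0.005, fxy_noise_sd = 2) {
  check_number(duration, "duration", positive = TRUE)
  check_number(fs, "fs", positive = TRUE)
  sw <- profile$sway
  n <- round(duration * fs)
  dt <- 1 / fs
  with_seed(seed, {
    ml <- ou_path(n, sw$theta_ml, sw$sigma_ml, sw$cop_offset_ml, dt)
    ap <- ou_path(n, sw$theta_ap, sw$sigma_ap, sw$cop_offset_ap, dt)
    ch <- channels_from_cop(ml, ap, profile$mass, fs,
      fz_noise_rel = fz_noise_rel, fxy_noise_sd = fxy_noise_sd)
    forceplate_trial(
      bind_cols(tibble(time = (seq_len(n) - 1) / fs), ch),
      fs = fs,
      meta = list(
        subject_id = profile$subject_id, group = profile$group,
        session = profile$session, test_type = "standing",
        mass = profile$mass, age = profile$age, sex = profile$sex,
        bmi = profile$bmi, seed = seed, events = list(),
        latent_cop = tibble(ml = ml, ap = ap)
      )
    )
  })
}

# Deterministic APA template (mm, relative to baseline) sampled at times t (s).
gait_template <- function(t, gp) {
  ml <- numeric(length(t))
  ap <- numeric(length(t))
  t0 <- gp$cue_time
  tl <- gp$loading_duration
  tu <- gp$unloading_duration
  A <- gp$apa_ml_amplitude
  B <- gp$apa_ap_amplitude
  load <- t >= t0 & t < t0 + tl
  s <- (t[load] - t0) / tl
  ml[load] <- A * (1 - cos(pi * s)) / 2
  ap[load] <- B * (1 - cos(pi * s)) / 2
  unload <- t >= t0 + tl & t < t0 + tl + tu
  u <- (t[unload] - t0 - tl) / tu
  ml[unload] <- A * cos(pi * u)
  # forward (anterior) progression of the COP as the step unfolds
  ap[unload] <- B + (0.5 * abs(B) - B) * (1 - cos(pi * u)) / 2
  after <- t >= t0 + tl + tu
  ml[after] <- -A
  ap[after] <- 0.5 * abs(B)
  list(ml = ml, ap = ap)
}

#' Simulate a gait-initiation force-plate trial
#'
#' The latent COP holds the subject's baseline for `cue_time` seconds, then
#' follows the anticipatory postural adjustment template of
#' [gait_params()]: lateral/posterior loading excursion, then reversal towards
#' the stance side. Ground-truth phase boundaries (cue, onset, loading end,
#' unloading end = lateral baseline recrossing) are stored in the trial
#' metadata under `events`.
#'
#' @inheritParams simulate_standing_trial
#' @param duration Total trial length (s); defaults to the template length
#'   plus 1.5 s of follow-through.
#' @return A [forceplate_trial()] with `test_type = "gait_initiation"`.
#' @export
simulate_gait_initiation_trial <- function(profile, fs = 1000, seed = 1,
                                           duration = NULL,
                                           fz_noise_rel = 0.005,
                                           fxy_noise_sd = 2) {
  check_number(fs, "fs", positive = TRUE)
  gp <- profile$gait
  template_end <- gp$cue_time + gp$loading_duration + gp$unloading_duration
  if (is.null(duration)) duration <- template_end + 1.5
  check_number(duration, "duration", positive = TRUE)
  if (duration < template_end) {
    stopf("trial duration %g s cannot hold the template (needs >= %g s)",
      duration, template_end)
  }
  sw <- profile$sway
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  tmpl <- gait_template(t, gp)
  with_seed(seed, {
    ml <- sw$cop_offset_ml + tmpl$ml + gp$template_noise_sd * rnorm(n)
    ap <- sw$cop_offset_ap + tmpl$ap + gp$template_noise_sd * rnorm(n)
    ch <- channels_from_cop(ml, ap, profile$mass, fs,
      fz_noise_rel = fz_noise_rel, fxy_noise_sd = fxy_noise_sd)
    forceplate_trial(
      bind_cols(tibble(time = t), ch),
      fs = fs,
      meta = list(
        subject_id = profile$subject_id, group = profile$group,
        session = profile$session, test_type = "gait_initiation",
        mass = profile$mass, age = profile$age, sex = profile$sex,
        bmi = profile$bmi, seed = seed,
        events = list(
          cue = gp$cue_time,
          onset = gp$cue_time,
          loading_end = gp$cue_time + gp$loading_duration,
          # half-cosine reversal crosses the baseline at its midpoint
          unloading_end = gp$cue_time + gp$loading_duration +
            gp$unloading_duration / 2
        ),
        latent_cop = tibble(ml = ml, ap = ap)
      )
    )
  })
}
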