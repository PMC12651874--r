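test_that("noise-free sway is a fixed point with zero standing features", {
  prof <- subject_profile("S0", "healthy", "single", mass = 70,
    sway = sway_params(sigma_ml = 0, sigma_ap = 0,
      cop_offset_ml = 4, cop_offset_ap = -3))
  tr <- simulate_standing_trial(prof, duration = 5, fs = 200, seed = 1,
    fz_noise_rel = 0, fxy_noise_sd = 0)
  cop <- compute_cop(tr)
  expect_equal(cop$ml, rep(4, nrow(cop)), tolerance = 1e-12)
  expect_equal(cop$ap, rep(-3, nrow(cop)), tolerance = 1e-12)
  f <- standing_features(cop)
  expect_equal(f$pl_total, 0)
  expect_equal(f$rms_ml, 0)
  expect_equal(f$sway_area, 0)
})

test_that("standing RMS converges to the stationary closed form sigma/sqrt(2 theta)", {
  prof <- subject_profile("S1", "healthy", "single",
    sway = sway_params(theta_ml = 1, theta_ap = 1, sigma_ml = 2, sigma_ap = 2))
  tr <- simulate_standing_trial(prof, duration = 300, fs = 100, seed = 7,
    fz_noise_rel = 0, fxy_noise_sd = 0)
  cop <- compute_cop(tr)
  target <- 2 / sqrt(2)  # 1.4142 mm
  expect_lt(abs(sqrt(mean((cop$ml - mean(cop$ml))^2)) - target) / target, 0.10)
  expect_lt(abs(sqrt(mean((cop$ap - mean(cop$ap))^2)) - target) / target, 0.10)
})

test_that("moment channels are mechanically consistent with the latent COP", {
  prof <- subject_profile("S2", "pd_control", "pre", mass = 82)
  tr <- simulate_standing_trial(prof, duration = 3, fs = 500, seed = 3)
  cop <- compute_cop(tr)
  lat <- trial_meta(tr)$latent_cop
  expect_lt(max(abs(cop$ml - lat$ml)), 1e-9)
  expect_lt(max(abs(cop$ap - lat$ap)), 1e-9)
  # scale the channels jointly: COP is unchanged
  tr2 <- tr
  tr2$Fz <- tr$Fz * 2; tr2$Mx <- tr$Mx * 2; tr2$My <- tr$My * 2
  cop2 <- compute_cop(tr2)
  expect_equal(cop2$ml, cop$ml, tolerance = 1e-12)
})

test_that("invalid durations and rates are rejected", {
  prof <- subject_profile("S3", "healthy", "single")
  expect_error(simulate_standing_trial(prof, duration = -1), "> 0")
  expect_error(simulate_standing_trial(prof, fs = 0), "> 0")
  expect_error(sway_params(theta_ml = 0), "> 0")
  expect_error(gait_params(cue_time = 0.5), ">= 1")
})

test_that("gait template carries truth boundaries, cue at 3 s by default", {
  prof <- subject_profile("S4", "pd_tpei", "pre",
    gait = gait_params(apa_ml_amplitude = 30, template_noise_sd = 0))
  tr <- simulate_gait_initiation_trial(prof, fs = 500, seed = 2,
    fz_noise_rel = 0, fxy_noise_sd = 0)
  ev <- trial_meta(tr)$events
  expect_equal(ev$cue, 3)
  expect_equal(ev$onset, 3)
  expect_equal(ev$loading_end, 3.5)
  # noise-free loading-phase ML displacement equals the template amplitude
  cop <- preprocess_trial(tr)
  ph <- segment_gait_initiation(cop)
  gf <- gait_features(cop, ph)
  expect_equal(gf$ldisp, 30, tolerance = 0.02)
  expect_lt(abs(ph$loading_end - ev$loading_end), 0.01)
  expect_lt(abs(ph$unloading_end - ev$unloading_end), 0.05)
})

test_that("PD-scaled APA amplitude is recovered as a 0.6 displacement ratio", {
  ratio <- vapply(1:50, function(s) {
    h <- simulate_gait_initiation_trial(
      subject_profile("H", "healthy", "single",
        gait = gait_params(apa_ml_amplitude = 30, template_noise_sd = 0.5)),
      fs = 200, seed = s)
    p <- simulate_gait_initiation_trial(
      subject_profile("P", "pd_control", "pre",
        gait = gait_params(apa_ml_amplitude = 18, template_noise_sd = 0.5)),
      fs = 200, seed = s + 5000)
    ch <- preprocess_trial(h); cp <- preprocess_trial(p)
    c(gait_features(cp, segment_gait_initiation(cp))$ldisp,
      gait_features(ch, segment_gait_initiation(ch))$ldisp)
  }, numeric(2))
  expect_lt(abs(mean(ratio[1, ]) / mean(ratio[2, ]) - 0.6) / 0.6, 0.05)
})

test_that("cohort bookkeeping, truth table and determinism hold", {
  cfg <- cohort_config(n_healthy = 2, n_pd_control = 2, n_pd_tpei = 2,
    fs = 50, standing_duration = 4)
  coh <- simulate_cohort(cfg, seed = 9)
  # 2 healthy x 1 session + 4 PD x 2 sessions = 10 subject-sessions, x2 tests
  expect_equal(nrow(coh$profiles), 10)
  expect_length(coh$trials, 20)
  expect_equal(nrow(coh$truth), 10)
  coh2 <- simulate_cohort(cfg, seed = 9)
  expect_identical(coh$truth, coh2$truth)
  expect_identical(
    as.data.frame(coh$trials[[5]]), as.data.frame(coh2$trials[[5]]))
  coh3 <- simulate_cohort(cfg, seed = 10)
  expect_false(identical(as.data.frame(coh$trials[[1]]),
    as.data.frame(coh3$trials[[1]])))
})

test_that("written cohorts are byte-identical across runs and round-trip", {
  cfg <- cohort_config(n_healthy = 1, n_pd_control = 1, n_pd_tpei = 1,
    fs = 50, standing_duration = 2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(cfg, seed = 4), d1)
  write_cohort(simulate_cohort(cfg, seed = 4), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
      info = f)
  }
  back <- read_cohort(d1)
  expect_equal(nrow(back$profiles), 5)
  tr0 <- simulate_cohort(cfg, seed = 4)$trials[[1]]
  tr1 <- back$trials[[names(simulate_cohort(cfg, seed = 4)$trials)[1]]]
  expect_equal(tr1$Fz, tr0$Fz, tolerance = 1e-12)
})

test_that("group sway contrast yields a huge negative RMS-ML effect size", {
  rms_of <- function(sigma, seed) {
    prof <- subject_profile("X", "healthy", "single",
      sway = sway_params(sigma_ml = sigma, sigma_ap = 1))
    tr <- simulate_standing_trial(prof, duration = 30, fs = 50, seed = seed,
      fz_noise_rel = 0, fxy_noise_sd = 0)
    cop <- compute_cop(tr)
    sqrt(mean((cop$ml - mean(cop$ml))^2))
  }
  healthy <- vapply(1:20, function(s) rms_of(1, s), numeric(1))
  pd <- vapply(1:20, function(s) rms_of(3, s + 900), numeric(1))
  d <- cohens_d(healthy, pd)
  expect_lt(d$d, 0)
  expect_gt(abs(d$d), 2)
  expect_equal(d$magnitude, "huge")
})

test_that("empty groups and invalid configs are rejected", {
  expect_error(cohort_config(n_healthy = 0), ">= 1")
  expect_error(cohort_config(intervention_shift = 1.2), "\\[0, 1\\]")
  expect_error(subject_profile("a", "healthy", "pre"), "single")
})
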