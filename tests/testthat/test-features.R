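sine_cop <- function(r = 5, f = 0.5, cycles = 10, fs = 1000) {
  t <- seq(0, cycles / f, by = 1 / fs)
  cop_trajectory(t, numeric(length(t)), r * sin(2 * pi * f * t), fs = fs)
}

test_that("sinusoidal sway reproduces analytic path length, RMS and velocity", {
  cop <- sine_cop()
  f <- standing_features(cop)
  expect_equal(f$pl_ap, 200, tolerance = 0.01)       # 4 r per cycle x 10
  expect_equal(f$rms_ap, 5 / sqrt(2), tolerance = 0.01)
  expect_equal(f$vmean_ap, 10, tolerance = 0.01)     # 200 mm / 20 s
  expect_equal(f$pl_ml, 0)
  expect_equal(f$var_ap, f$rms_ap^2, tolerance = 1e-9)
})

test_that("a uniform circle gives the 95% prediction-ellipse sway area", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)
  cop <- cop_trajectory(t, 5 * cos(2 * pi * 0.3 * t), 5 * sin(2 * pi * 0.3 * t), fs = fs)
  f <- standing_features(cop)
  expect_equal(f$sway_area, qchisq(0.95, 2) * pi * 25 / 2, tolerance = 0.01)
})

test_that("standing features scale homogeneously and ignore offsets", {
  set.seed(42)
  n <- 2000
  cop <- cop_trajectory((1:n) / 100, cumsum(rnorm(n, 0, 0.2)),
    cumsum(rnorm(n, 0, 0.2)), fs = 100)
  f1 <- standing_features(cop)
  c3 <- cop_trajectory(cop$time, 3 * cop$ml, 3 * cop$ap, fs = 100)
  f3 <- standing_features(c3)
  for (col in c("pl_ml", "pl_ap", "pl_total", "rms_ml", "rms_ap",
                "vmean_ml", "vmean_ap", "vmean_total")) {
    expect_equal(f3[[col]], 3 * f1[[col]], tolerance = 1e-9, info = col)
  }
  expect_equal(f3$sway_area, 9 * f1$sway_area, tolerance = 1e-9)
  off <- cop_trajectory(cop$time, cop$ml + 11, cop$ap - 4, fs = 100)
  expect_equal(standing_features(off)$rms_ml, f1$rms_ml, tolerance = 1e-12)
  # path length dominates net displacement per axis
  expect_gte(f1$pl_ml, abs(cop$ml[n] - cop$ml[1]))
})

test_that("features are sampling-rate robust for band-limited sway", {
  fs <- 1000
  t <- seq(0, 20, by = 1 / fs)
  ml <- 4 * sin(2 * pi * 0.4 * t) + 2 * sin(2 * pi * 1.1 * t)
  ap <- 3 * cos(2 * pi * 0.6 * t)
  hi <- standing_features(cop_trajectory(t, ml, ap, fs = fs))
  keep <- seq(1, length(t), by = 2)
  lo <- standing_features(cop_trajectory(t[keep], ml[keep], ap[keep], fs = fs / 2))
  for (col in c("pl_ml", "pl_ap", "rms_ml", "rms_ap", "vmean_ml", "sway_area")) {
    expect_lt(abs(lo[[col]] - hi[[col]]) / hi[[col]], 0.02, label = col)
  }
})

test_that("onset detection fires at a sustained threshold crossing", {
  fs <- 200
  t <- seq(0, 8, by = 1 / fs)
  set.seed(1)
  ml <- rnorm(length(t), sd = 0.5)
  dev_sd <- sd(abs(ml[t < 3]))
  ml[t >= 4] <- ml[t >= 4] + 10 * dev_sd + 20
  cop <- cop_trajectory(t, ml, numeric(length(t)), fs = fs,
    meta = list(events = list(cue = 3)))
  ph <- segment_gait_initiation(cop)
  expect_equal(ph$onset, 4, tolerance = 0.02)
})

test_that("no-movement trajectories raise a detection error", {
  fs <- 100
  t <- seq(0, 6, by = 1 / fs)
  set.seed(2)
  cop <- cop_trajectory(t, rnorm(length(t), sd = 0.3), rnorm(length(t), sd = 0.3),
    fs = fs, meta = list(events = list(cue = 3)))
  expect_error(segment_gait_initiation(cop), "no initiation")
})

test_that("noisy templates keep boundary errors within 50 ms in >= 90% of trials", {
  errs <- vapply(1:50, function(s) {
    tr <- simulate_gait_initiation_trial(
      subject_profile("E", "pd_tpei", "pre",
        gait = gait_params(apa_ml_amplitude = 30, template_noise_sd = 1)),
      fs = 200, seed = s)
    cop <- preprocess_trial(tr)
    ph <- segment_gait_initiation(cop)
    ev <- trial_meta(tr)$events
    max(abs(ph$loading_end - ev$loading_end),
      abs(ph$unloading_end - ev$unloading_end))
  }, numeric(1))
  expect_gte(mean(errs <= 0.05), 0.9)
})

test_that("gait displacement and velocity arithmetic is exact", {
  fs <- 100
  t <- seq(0, 6, by = 1 / fs)
  ml <- numeric(length(t))
  ml[t >= 3 & t < 3.5] <- 40 * (t[t >= 3 & t < 3.5] - 3)  # ramp to 20 mm
  ml[t >= 3.5] <- 20 - 60 * (t[t >= 3.5] - 3.5)
  cop <- cop_trajectory(t, ml, numeric(length(t)), fs = fs)
  phases <- structure(list(onset = 3, loading_end = 3.5, unloading_end = 4),
    class = "gait_phases")
  gf <- gait_features(cop, phases)
  expect_equal(gf$ldisp, 20, tolerance = 1e-9)
  expect_equal(gf$lvel_ml, 40, tolerance = 1e-9)
  expect_equal(gf$udisp_ml, 30, tolerance = 1e-9)
  bad <- structure(list(onset = 3, loading_end = 3, unloading_end = 4),
    class = "gait_phases")
  expect_error(gait_features(cop, bad), "zero-length")
})

test_that("channel SDs follow the sample definition and its symmetries", {
  n <- 40
  tr <- forceplate_trial(
    tibble::tibble(time = (1:n) / 100, Fx = rep(c(-3, 3), n / 2),
      Fy = 0, Fz = 700, Mx = 1, My = 1, Mz = 0),
    fs = 100, meta = list())
  cop <- compute_cop(tr)
  sds <- signal_sd_features(tr, cop)
  expect_equal(sds$sd_fx, 3 * sqrt(n / (n - 1)), tolerance = 1e-12)
  expect_equal(sds$sd_fy, 0)
  expect_equal(sds$sd_cop_ml, 0, tolerance = 1e-9)
  tr2 <- tr; tr2$Fx <- tr$Fx * -2.5
  expect_equal(signal_sd_features(tr2, cop)$sd_fx, 2.5 * sds$sd_fx,
    tolerance = 1e-12)
})

test_that("feature tables assemble one row per subject-session with provenance", {
  demo <- tidyr::crossing(
    tibble::tibble(subject_id = sprintf("P%02d", 1:12)),
    tibble::tibble(session = c("pre", "post"))) |>
    dplyr::mutate(group = "pd_control", age = 60, sex = "M", bmi = 25)
  demo <- dplyr::bind_rows(demo, tibble::tibble(
    subject_id = sprintf("H%02d", 1:6), session = "single",
    group = "healthy", age = 25, sex = "F", bmi = 22))
  blk <- demo[, c("subject_id", "session")]
  blk$rms_ml <- seq_len(nrow(blk))
  tab <- build_feature_table(list(standing = blk), demo)
  expect_equal(nrow(tab), 30)
  expect_setequal(feature_names(tab), c("rms_ml", "age", "sex", "bmi"))
  expect_equal(attr(tab, "provenance")$standing, "rms_ml")
  expect_true(all(tab$sex[tab$group == "healthy"] == 1))

  demo_dup <- dplyr::bind_rows(demo, demo[1, ])
  expect_error(build_feature_table(list(standing = blk), demo_dup), "duplicate")
  expect_error(build_feature_table(list(standing = blk[-3, ]), demo), "missing block")
})

test_that("standardisation is a column z-score, idempotent, and guards variance", {
  demo <- tibble::tibble(subject_id = sprintf("S%d", 1:8), session = "pre",
    group = "pd_control", age = c(50:57), sex = rep(c("M", "F"), 4),
    bmi = rnorm(8, 25))
  blk <- demo[, c("subject_id", "session")]
  blk$f1 <- rnorm(8); blk$f2 <- runif(8)
  tab <- build_feature_table(list(b = blk), demo)
  std <- standardize_features(tab)
  for (f in c("f1", "f2", "age", "bmi")) {
    expect_lt(abs(mean(std[[f]])), 1e-9)
    expect_equal(sd(std[[f]]), 1, tolerance = 1e-9)
  }
  again <- standardize_features(std)
  expect_equal(again$f1, std$f1, tolerance = 1e-12)
  expect_true(attr(std, "standardized"))
  blk$f3 <- 5
  tab2 <- build_feature_table(list(b = blk), demo, include_demographics = FALSE)
  expect_error(standardize_features(tab2), "zero-variance.*f3")
})

test_that("cohort feature extraction covers the configured blocks", {
  coh <- tiny_cohort(seed = 3, fs = 100,
    n_healthy = 2, n_pd_control = 2, n_pd_tpei = 2, standing_duration = 8)
  tab <- cohort_feature_table(coh)
  expect_equal(nrow(tab), 10)
  expect_true(all(c("rms_ml", "pl_ap", "ldisp", "sd_fx", "age") %in% names(tab)))
  expect_false(any(is.na(as.data.frame(tab))))
  sd_only <- cohort_feature_table(coh, blocks = "signal_sd",
    include_demographics = FALSE)
  expect_setequal(feature_names(sd_only),
    c("sd_fx", "sd_fy", "sd_fz", "sd_mx", "sd_my", "sd_mz",
      "sd_cop_ml", "sd_cop_ap"))
})
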