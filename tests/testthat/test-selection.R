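sep_data <- function(n = 40, noise = 5, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(0, 1), each = n / 2)
    x <- as.data.frame(matrix(rnorm(n * noise), n))
    names(x) <- paste0("noise", seq_len(noise))
    x$signal <- y * 4 + rnorm(n, sd = 0.5)
    list(x = x[, sample(names(x))], y = y)
  })
}

test_that("a perfectly informative column is found first in nearly all runs", {
  hits <- vapply(1:60, function(s) {
    d <- sep_data(n = 30, noise = 8, seed = s)
    sel <- forward_select(d$x, d$y, classifier_spec("logistic_regression"),
      target_size = 1, cv_repeats = 2, seed = s)
    sel$selected[1] == "signal"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("selection stops at the target size and handles the empty case", {
  d <- sep_data(seed = 2)
  expect_equal(forward_select(d$x, d$y, target_size = 0)$selected, character(0))
  sel <- forward_select(d$x, d$y, target_size = 2, seed = 1)
  expect_length(sel$selected, 2)
  expect_equal(sel$trace$step, 1:2)
})

test_that("duplicated informative columns tie and break by column order", {
  withr::with_seed(5, {
    y <- rep(c(0, 1), each = 12)
    x <- data.frame(a = y + rnorm(24, sd = 0.1))
    x$b <- x$a
    x <- x[, c("a", "b")]
  })
  sel <- forward_select(x, y, classifier_spec("logistic_regression"),
    target_size = 1, seed = 3)
  expect_equal(sel$selected, "a")
  expect_true("1" %in% names(sel$ties))
  expect_setequal(sel$ties[["1"]], c("a", "b"))
})

test_that("greedy scores are non-decreasing while useful features remain", {
  d <- sep_data(n = 40, noise = 3, seed = 11)
  d$x$signal2 <- d$y * 3 + rnorm(40, sd = 0.6)
  sel <- forward_select(d$x, d$y, classifier_spec("logistic_regression"),
    target_size = 2, seed = 7)
  expect_gte(sel$trace$score[2], sel$trace$score[1] - 1e-12)
})

test_that("nested CV leaves one subject out and scores each fold", {
  coh <- tiny_cohort(seed = 5, fs = 100, standing_duration = 8,
    test_types = "standing")
  tab <- cohort_feature_table(coh, blocks = "standing")
  pre <- tab$session != "post"
  std <- standardize_features(tab[pre, c("subject_id", "group", "session",
    "rms_ml", "pl_ap", "rms_ap", "pl_ml")])
  y <- as.integer(std$group != "healthy")
  rep <- nested_cv_evaluate(std[, c("rms_ml", "pl_ap", "rms_ap", "pl_ml")], y,
    groups = std$subject_id, target_size = 2, cv_repeats = 2, seed = 1)
  expect_length(rep$scores, 18)
  expect_equal(rep$mean, mean(rep$scores))
  expect_length(rep$selections, 18)
  # strongly separated groups classify perfectly out of sample
  expect_gte(rep$mean, 0.9)
})

test_that("nested CV under permuted labels matches the majority-class rate", {
  d <- sep_data(n = 24, noise = 3, seed = 3)
  groups <- rep(1:12, each = 2)
  means <- vapply(1:30, function(s) {
    yp <- withr::with_seed(s, {
      g_lab <- sample(rep(c(0, 1), each = 6))  # permute at subject level
      g_lab[groups]
    })
    nested_cv_evaluate(d$x, yp, groups, classifier_spec("k_nearest_neighbors", k = 3),
      target_size = 1, cv_repeats = 1, seed = s)$mean
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 0.5), 3 * max(se, 0.02))
})

test_that("bootstrap CIs collapse in degenerate settings", {
  d <- sep_data(n = 30, noise = 1, seed = 4)
  one <- bootstrap_metrics(d$x, d$y, selected = "signal", B = 1, seed = 1)
  expect_equal(one$ci[1], one$ci[2])
  expect_equal(one$ci[1], one$scores[1])
  # a perfectly separated sample scores 1 on every resample: zero-width CI
  all_b <- bootstrap_metrics(d$x, d$y, selected = "signal", B = 50, seed = 2)
  expect_equal(all_b$ci, c(1, 1))
  expect_equal(all_b$sd, 0)
})

test_that("permutation p-values hit the analytic extremes", {
  d <- sep_data(n = 30, noise = 2, seed = 6)
  p <- permutation_test(d$x, d$y, selected = "signal", B = 199, seed = 1)
  expect_equal(p$p_value, 1 / 200)
  # a constant feature gives the same majority-vote metric for any labelling
  const <- data.frame(flat = rep(1, 30))
  p1 <- permutation_test(const, d$y, spec = classifier_spec("logistic_regression"),
    selected = "flat", B = 49, seed = 2)
  expect_equal(p1$p_value, 1)
})

test_that("McFadden pseudo-R2 matches a direct likelihood-optimisation oracle", {
  x <- data.frame(x = c(-2, 1, -1, 2, -1.5, 0.5))
  y <- c(0, 0, 1, 1, 0, 1)
  got <- mcfadden_r2(x, y)
  nll <- function(b) {
    eta <- b[1] + b[2] * x$x
    -sum(y * eta - log1p(exp(eta)))
  }
  opt <- optim(c(0, 0), nll, method = "BFGS")
  ll0 <- sum(y) * log(mean(y)) + sum(1 - y) * log(1 - mean(y))
  expect_equal(as.numeric(got), 1 - (-opt$value) / ll0, tolerance = 1e-5)
  expect_false(attr(got, "separation"))
})

test_that("McFadden pseudo-R2 behaves at the null and separation limits", {
  withr::with_seed(9, {
    x <- data.frame(a = rnorm(200), b = rnorm(200))
    y <- rep(c(0, 1), 100)
  })
  expect_lt(as.numeric(mcfadden_r2(x, y)), 0.02)
  xs <- data.frame(a = c(rnorm(30, -4), rnorm(30, 4)))
  ys <- rep(c(0, 1), each = 30)
  rs <- mcfadden_r2(xs, ys)
  expect_gt(as.numeric(rs), 0.9)
  expect_true(attr(rs, "separation"))
})

test_that("planted sway features are recovered by at least one wrapper", {
  both <- c("rms_ml", "pl_ap")
  hits <- vapply(1:12, function(s) {
    coh <- simulate_cohort(cohort_config(fs = 125, variant = "signal_recovery",
      test_types = "standing"), seed = s)
    tab <- cohort_feature_table(coh, blocks = c("standing", "signal_sd"))
    pre <- tab$session != "post"
    cand <- c("rms_ml", "pl_ap", "sd_fx", "sd_fy", "age", "bmi")
    std <- standardize_features(tab[pre, c("subject_id", "group", "session", cand)])
    y <- as.integer(std$group != "healthy")
    lr <- forward_select(std[, cand], y, classifier_spec("logistic_regression"),
      target_size = 3, cv_repeats = 4, seed = s)
    kn <- forward_select(std[, cand], y, classifier_spec("k_nearest_neighbors"),
      target_size = 3, cv_repeats = 4, seed = s + 1)
    all(both %in% lr$selected) || all(both %in% kn$selected)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
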