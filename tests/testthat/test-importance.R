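test_that("null forests spread importance evenly over exchangeable features", {
  cfg <- null_synthetic_config(seed = 41, n = 150L)
  cfg$within_block_corr[] <- 0  # fully exchangeable task features
  co <- generate_cohort(cfg)
  fm <- build_feature_matrix(co, include_age_gender = FALSE)
  split <- split_train_test(fm, 0.8, seed = 1)
  nul <- null_forest_importances(fm, split,
                                 rf_hyperparams(30, "sqrt", TRUE, 4, 10),
                                 n_repetitions = 60, seed = 2)
  means <- colMeans(nul$importance)
  p <- length(means)
  se <- apply(nul$importance, 2, sd) / sqrt(nrow(nul$importance))
  expect_true(all(abs(means - 1 / p) < 3 * se + 0.005))
  expect_equal(unname(rowSums(nul$importance)), rep(1, 60))
})

test_that("an identity relabeling reproduces the real-label fit", {
  fm <- tiny_feature_matrix(n = 150, seed = 43, signal = 1)
  split <- split_train_test(fm, 0.8, seed = 44)
  hp <- rf_hyperparams(10, "sqrt", TRUE, 4, 10)
  real <- fit_forest(fm, hp, seed = 5, rows = split$train_indices)
  forced <- fit_forest(fm, hp, seed = 5, rows = split$train_indices,
                       labels = fm$labels[split$train_indices])
  expect_identical(real$trees, forced$trees)
  expect_equal(real$importance, forced$importance)
})

test_that("the importance t-test matches a closed-form Welch oracle", {
  p <- 56
  reps <- 400
  set.seed(46)
  feature_names <- sprintf("v%02d", 1:p)
  real <- matrix(rnorm(reps * p, 0.02, 0.01), reps, p,
                 dimnames = list(NULL, feature_names))
  null <- matrix(rnorm(reps * p, 0.02, 0.01), reps, p,
                 dimnames = list(NULL, feature_names))
  real[, 1] <- rnorm(reps, 0.10, 0.01)  # one strongly elevated feature

  inf <- test_significance(real, null, alpha = 0.05)
  expect_true(inf$significant[1])
  expect_equal(inf$p_bonferroni, pmin(1, inf$p_raw * p))

  # closed-form Welch statistic for the elevated column
  m1 <- mean(real[, 1]); m0 <- mean(null[, 1])
  v1 <- var(real[, 1]); v0 <- var(null[, 1])
  t_oracle <- (m1 - m0) / sqrt(v1 / reps + v0 / reps)
  expect_equal(inf$t_stat[1], t_oracle, tolerance = 1e-12)
  df <- (v1 / reps + v0 / reps)^2 /
    ((v1 / reps)^2 / (reps - 1) + (v0 / reps)^2 / (reps - 1))
  expect_equal(inf$p_raw[1], 2 * pt(-abs(t_oracle), df), tolerance = 1e-9)

  # identical columns: t = 0, p = 1, never significant
  same <- null
  inf_same <- test_significance(same, null, alpha = 0.05)
  expect_equal(inf_same$t_stat, rep(0, p))
  expect_equal(inf_same$p_raw, rep(1, p))
  expect_false(any(inf_same$significant))

  # alpha = 0 switches everything off
  expect_false(any(test_significance(real, null, alpha = 0)$significant))

  # a significant flag requires the real mean to exceed the null mean
  depressed <- real
  depressed[, 2] <- rnorm(reps, 0.002, 0.001)
  inf_dep <- test_significance(depressed, null)
  expect_lt(inf_dep$p_bonferroni[2], 0.05)
  expect_false(inf_dep$significant[2])
})

test_that("the permutation method is calibrated when real equals null", {
  p <- 30
  set.seed(47)
  nm <- sprintf("v%02d", 1:p)
  flagged <- replicate(10, {
    real <- matrix(rnorm(100 * p, 0.02, 0.01), 100, p,
                   dimnames = list(NULL, nm))
    null <- matrix(rnorm(100 * p, 0.02, 0.01), 100, p,
                   dimnames = list(NULL, nm))
    mean(test_significance(real, null, method = "permutation")$significant)
  })
  expect_lte(mean(flagged), 0.05)
})

test_that("partial dependence matches the brute-force clamp oracle", {
  fm <- tiny_feature_matrix(n = 120, seed = 48, signal = 1.5)
  data <- fm$values

  # a forest that never uses f3 yields a flat curve
  no_f3 <- fm
  no_f3$values[, "f3"] <- 0  # constant: cannot be split on
  forest <- fit_forest(no_f3, rf_hyperparams(5, "all", TRUE, 3, 10), seed = 1)
  expect_equal(unname(forest$importance["f3"]), 0)
  curve <- partial_dependence(forest, "f3", no_f3$values,
                              grid = seq(-2, 2, length.out = 9))
  expect_equal(length(unique(curve$mean_prediction)), 1)

  # a single stump is a step function at its threshold
  stump <- fit_forest(fm, rf_hyperparams(1, "all", FALSE, 1, 10), seed = 2)
  threshold <- stump$trees[[1]]$splitval[1]
  curve <- partial_dependence(stump, "f1", data,
                              grid = c(threshold - 0.5, threshold - 1e-9,
                                       threshold + 1e-9, threshold + 0.5))
  expect_equal(curve$mean_prediction[1], curve$mean_prediction[2])
  expect_equal(curve$mean_prediction[3], curve$mean_prediction[4])
  expect_false(curve$mean_prediction[2] == curve$mean_prediction[3])

  # a three-tree forest agrees with naive clamp-and-average exactly
  forest3 <- fit_forest(fm, rf_hyperparams(3, "sqrt", TRUE, 4, 10), seed = 3)
  grid <- seq(-2, 2, length.out = 7)
  curve <- partial_dependence(forest3, "f2", data, grid = grid)
  expect_equal(curve$mean_prediction,
               oracle_partial_dependence(forest3, "f2", data, grid))

  expect_error(partial_dependence(forest3, "nope", data), "unknown feature")
  expect_error(partial_dependence(forest3, "f1", data, grid = numeric(0)),
               "empty")
})

test_that("simulated strong and joint-signal features are recovered", {
  co <- generate_cohort(synthetic_config(seed = 3, n_autistic = 125,
                                         n_nonautistic = 125))
  fm <- build_feature_matrix(co)
  split <- split_train_test(fm, 0.8, seed = 1974)
  hp <- rf_hyperparams(50, "sqrt", TRUE, 5, 10)
  real <- repeat_fit(fm, split, hp, n_repetitions = 60, seed = 42)
  nul <- null_forest_importances(fm, split, hp, n_repetitions = 60, seed = 97)
  inf <- test_significance(real, nul)
  strong <- names(which(default_effect_profile() >= 0.5))
  expect_true(all(inf$significant[match(strong, inf$feature)]))
  expect_true(all(inf$significant[match(c("gng_03", "cbd_04"), inf$feature)]))
})
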