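test_that("hyperparameter objects validate their fields", {
  hp <- rf_hyperparams()
  expect_equal(hp$n_estimators, 100L)
  expect_equal(hp$max_depth, 4L)
  expect_true(hp$bootstrap)
  expect_false(matched_hyperparams()$bootstrap)
  expect_equal(matched_hyperparams()$max_depth, 3L)
  expect_error(rf_hyperparams(max_depth = 0))
  expect_error(rf_hyperparams(max_features = "cube"))
  expect_equal(forestscreen:::resolve_mtry("sqrt", 56), 7L)
  expect_equal(forestscreen:::resolve_mtry("sqrt", 57), 7L)
  expect_equal(forestscreen:::resolve_mtry("log2", 56), 5L)
  expect_equal(forestscreen:::resolve_mtry("all", 56), 56L)
})

test_that("a one-tree depth-one forest is a single decision stump", {
  fm <- tiny_feature_matrix(n = 100, seed = 2, signal = 2)
  hp <- rf_hyperparams(n_estimators = 1, max_depth = 1,
                       min_samples_leaf = 10, max_features = "all")
  forest <- fit_forest(fm, hp, seed = 1)
  tree <- forest$trees[[1]]
  expect_equal(nrow(tree), 3)
  expect_equal(sum(!tree$terminal), 1)
  expect_equal(tree$splitvarName[1], "f1")  # the only signal feature
})

test_that("depth and leaf-size constraints hold over every fitted tree", {
  fm <- tiny_feature_matrix(n = 200, p = 8, seed = 3, signal = 1)
  depth_of <- function(tree) {
    walk <- function(i, d) {
      if (tree$terminal[i + 1]) return(d)
      max(walk(tree$leftChild[i + 1], d + 1),
          walk(tree$rightChild[i + 1], d + 1))
    }
    walk(0L, 0L)
  }
  for (hp in list(rf_hyperparams(20, "sqrt", TRUE, 3, 15),
                  rf_hyperparams(20, "sqrt", FALSE, 6, 5),
                  rf_hyperparams(10, "all", TRUE, 2, 40))) {
    forest <- fit_forest(fm, hp, seed = 4)
    expect_lte(max(vapply(forest$trees, depth_of, numeric(1))), hp$max_depth)
    min_leaf <- min(vapply(forest$trees, function(t) {
      min(t$n_node[t$terminal])
    }, numeric(1)))
    expect_gte(min_leaf, hp$min_samples_leaf)
  }
})

test_that("a 60-row leaf floor at depth 3 caps trees at three leaves", {
  fm <- tiny_feature_matrix(n = 200, p = 10, seed = 5, signal = 1.5)
  forest <- fit_forest(fm, rf_hyperparams(25, "sqrt", FALSE, 3, 60), seed = 6)
  leaves <- vapply(forest$trees, function(t) sum(t$terminal), integer(1))
  expect_lte(max(leaves), 3)
})

test_that("fitting is deterministic given the seed", {
  fm <- tiny_feature_matrix(n = 150, seed = 7, signal = 1)
  hp <- rf_hyperparams(10, "sqrt", TRUE, 4, 10)
  f1 <- fit_forest(fm, hp, seed = 9)
  f2 <- fit_forest(fm, hp, seed = 9)
  expect_identical(f1$trees, f2$trees)
  probe <- tiny_feature_matrix(n = 50, seed = 8)$values
  expect_identical(predict_forest(f1, probe), predict_forest(f2, probe))
  expect_error(fit_forest(
    structure(list(values = fm$values, feature_names = fm$feature_names,
                   labels = rep(1L, 150),
                   participant_ids = fm$participant_ids),
              class = "feature_matrix"), hp), "single class")
})

test_that("forest prediction equals the per-tree majority-vote oracle", {
  fm <- tiny_feature_matrix(n = 120, seed = 10, signal = 1)
  probe <- tiny_feature_matrix(n = 40, seed = 11)$values
  for (ntree in c(1, 3, 5)) {
    forest <- fit_forest(fm, rf_hyperparams(ntree, "sqrt", TRUE, 4, 5),
                         seed = ntree)
    pred <- predict_forest(forest, probe)
    votes <- oracle_votes(forest, probe)
    expect_equal(pred$votes, votes)
    expect_equal(pred$class, as.integer(votes > 0.5))
  }
})

test_that("trees and importance are invariant to feature rescaling", {
  fm <- tiny_feature_matrix(n = 150, seed = 12, signal = 1)
  scaled <- fm
  scaled$values <- fm$values * 1000
  hp <- rf_hyperparams(10, "sqrt", TRUE, 4, 10)
  f <- fit_forest(fm, hp, seed = 13)
  fs <- fit_forest(scaled, hp, seed = 13)
  expect_equal(f$importance, fs$importance)
  same_structure <- mapply(function(a, b) {
    identical(a$splitvarName, b$splitvarName) &&
      isTRUE(all.equal(a$splitval, b$splitval * 1e-3))
  }, f$trees, fs$trees)
  expect_true(all(same_structure))
  probe <- tiny_feature_matrix(n = 30, seed = 14)$values
  expect_identical(predict_forest(f, probe)$class,
                   predict_forest(fs, probe * 1000)$class)
})

test_that("labels independent of features give chance-level test accuracy", {
  fm <- tiny_feature_matrix(n = 250, p = 20, seed = 15, signal = 0)
  split <- split_train_test(fm, 0.8, seed = 16)
  rr <- repeat_fit(fm, split, rf_hyperparams(30, "sqrt", TRUE, 4, 10),
                   n_repetitions = 30, seed = 17)
  expect_gt(mean(rr$metrics$test_accuracy), 0.4)
  expect_lt(mean(rr$metrics$test_accuracy), 0.6)
})

test_that("repeated fitting varies only forest-internal randomness", {
  fm <- tiny_feature_matrix(n = 150, seed = 18, signal = 1)
  split <- split_train_test(fm, 0.8, seed = 19)

  # a single repetition equals a direct fit under the derived seed
  hp <- rf_hyperparams(10, "sqrt", TRUE, 4, 10)
  rr <- repeat_fit(fm, split, hp, n_repetitions = 1, seed = 100)
  direct <- fit_forest(fm, hp, seed = 101, rows = split$train_indices)
  expect_equal(rr$importance[1, ], direct$importance)
  pred <- predict_forest(direct, fm$values[split$test_indices, ])
  perf <- performance(confusion(fm$labels[split$test_indices], pred$class))
  expect_equal(rr$metrics$test_f1[1], perf$f1)

  # no bootstrap + all features: no randomness source remains
  hp_det <- rf_hyperparams(5, "all", FALSE, 3, 10)
  rr_det <- repeat_fit(fm, split, hp_det, n_repetitions = 4, seed = 1)
  expect_equal(length(unique(rr_det$metrics$test_f1)), 1)
  expect_true(all(apply(rr_det$importance, 2, function(col) {
    length(unique(col)) == 1
  })))

  # with bootstrap the repetitions genuinely disperse
  rr_b <- repeat_fit(fm, split, hp, n_repetitions = 25, seed = 2)
  expect_gt(sd(rr_b$metrics$test_accuracy), 0)
})

test_that("refitting a repetition reproduces its forest exactly", {
  fm <- tiny_feature_matrix(n = 150, seed = 20, signal = 1)
  split <- split_train_test(fm, 0.8, seed = 21)
  hp <- rf_hyperparams(8, "sqrt", TRUE, 4, 10)
  rr <- repeat_fit(fm, split, hp, n_repetitions = 10, seed = 33,
                   keep_forests = TRUE)
  again <- refit_repetition(fm, rr, 6)
  expect_identical(again$trees, rr$forests[[6]]$trees)
  expect_equal(again$importance, rr$importance[6, ])
})

test_that("best-model selection maximizes test F1 with lowest-index ties", {
  fake <- data.frame(test_f1 = c(0.5, 0.9, 0.7))
  expect_equal(select_best(fake), 2)
  expect_equal(select_best(data.frame(test_f1 = rep(0.5, 4))), 1)
  expect_error(select_best(data.frame(test_f1 = numeric(0))), "no repetition")
})

test_that("selection bias is real: the best null-data model beats the median", {
  fm <- tiny_feature_matrix(n = 250, p = 20, seed = 22, signal = 0)
  split <- split_train_test(fm, 0.8, seed = 23)
  rr <- repeat_fit(fm, split, rf_hyperparams(30, "sqrt", TRUE, 4, 10),
                   n_repetitions = 40, seed = 24)
  best <- select_best(rr)
  expect_gt(rr$metrics$test_f1[best], median(rr$metrics$test_f1))
})

test_that("grid search picks the cross-validated F1 maximizer", {
  hp_ref <- rf_hyperparams()
  fm <- tiny_feature_matrix(n = 240, p = 6, seed = 25, signal = 2.5)

  # singleton grid: returns that setting
  tuned <- suppressWarnings(
    tune_hyperparameters(fm, grid = list(hp_ref), k_folds = 3, seed = 1))
  expect_equal(unclass(tuned)[names(unclass(hp_ref))], unclass(hp_ref))

  # separable data, depth 1 vs 6: chosen depth scores at least as well
  grid <- list(rf_hyperparams(20, "sqrt", TRUE, 1, 10),
               rf_hyperparams(20, "sqrt", TRUE, 6, 10))
  tuned <- tune_hyperparameters(fm, grid = grid, k_folds = 3, seed = 2)
  cv <- attr(tuned, "cv_results")
  chosen <- cv$mean_cv_score[cv$max_depth == tuned$max_depth]
  expect_gte(chosen, max(cv$mean_cv_score[cv$max_depth != tuned$max_depth]))
  expect_true(all(c("mean_train_score", "train_val_gap") %in% names(cv)))

  expect_error(tune_hyperparameters(fm, grid = list()), "empty")
})
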