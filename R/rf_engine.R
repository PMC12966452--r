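# Random-forest engine: hyperparameter handling, single fits, repeated
# fitting and best-model selection.  Trees are grown by the package's own
# compiled CART engine (src/forest.cpp): Gini criterion, per-split feature
# subsampling, optional bootstrap resampling, a hard depth limit and a hard
# minimum-leaf-size guarantee, with ties in the majority vote going to the
# non-autistic class and impurity importance normalized to sum to one.
# Every fitted tree is exposed as an explicit node table for downstream
# structure analysis (co-occurrence, partial dependence, oracle checks).

#' Random-forest hyperparameters
#'
#' The five tuned forest parameters.  The defaults are the optimum for the
#' full unmatched sample (100 trees, sqrt feature subsampling, bootstrap
#' resampling, depth 4, at least 60 participants per leaf);
#' [matched_hyperparams()] gives the optimum for the age/gender-matched
#' subsample (bootstrap off, depth 3).
#'
#' @param n_estimators number of trees in the forest.
#' @param max_features feature-subsampling rule per split: `"sqrt"`,
#'   `"log2"`, `"all"`, or a fixed integer count.
#' @param bootstrap draw a bootstrap resample per tree; when `FALSE` every
#'   tree sees the full training set and trees differ only through feature
#'   subsampling.
#' @param max_depth maximum number of levels per tree.
#' @param min_samples_leaf minimum number of training rows per leaf.
#' @return An object of class `rf_hyperparams`.
#' @export
rf_hyperparams <- function(n_estimators = 100L, max_features = "sqrt",
                           bootstrap = TRUE, max_depth = 4L,
                           min_samples_leaf = 60L) {
  stopifnot(n_estimators >= 1, max_depth >= 1, min_samples_leaf >= 1,
            is.logical(bootstrap), length(bootstrap) == 1)
  if (is.character(max_features)) {
    max_features <- match.arg(max_features, c("sqrt", "log2", "all"))
  } else {
    stopifnot(is.numeric(max_features), max_features >= 1)
    max_features <- as.integer(max_features)
  }
  structure(list(
    n_estimators = as.integer(n_estimators),
    max_features = max_features,
    bootstrap = bootstrap,
    max_depth = as.integer(max_depth),
    min_samples_leaf = as.integer(min_samples_leaf)
  ), class = "rf_hyperparams")
}

#' @rdname rf_hyperparams
#' @export
matched_hyperparams <- function() {
  rf_hyperparams(n_estimators = 100L, max_features = "sqrt",
                 bootstrap = FALSE, max_depth = 3L, min_samples_leaf = 60L)
}

resolve_mtry <- function(max_features, p) {
  if (is.character(max_features)) {
    switch(max_features,
           sqrt = max(1L, floor(sqrt(p))),
           log2 = max(1L, floor(log2(p))),
           all = p)
  } else {
    min(as.integer(max_features), p)
  }
}

# Node table (treeInfo-style data.frame) from one compiled tree.
tree_node_table <- function(tree, feature_names) {
  leaf <- tree$splitvar < 0L
  k <- length(tree$left)
  split_names <- rep(NA_character_, k)
  split_names[!leaf] <- feature_names[tree$splitvar[!leaf] + 1L]
  # direct list->data.frame assembly: this runs once per tree across
  # thousands of fitted forests, so skip data.frame()'s checking overhead
  structure(list(
    nodeID = seq_len(k) - 1L,
    leftChild = ifelse(leaf, NA_integer_, tree$left),
    rightChild = ifelse(leaf, NA_integer_, tree$right),
    splitvarID = ifelse(leaf, NA_integer_, tree$splitvar),
    splitvarName = split_names,
    splitval = tree$splitval,
    terminal = tree$terminal,
    prediction = tree$prediction,
    n_node = tree$n_node
  ), class = "data.frame", row.names = seq_len(k))
}

#' Fit a single random forest
#'
#' Grows `n_estimators` CART trees with the Gini criterion.  Each split
#' considers a fresh random subset of features (the `max_features` rule);
#' with `bootstrap = TRUE` each tree trains on a bootstrap resample of the
#' training rows (the leaf-size guarantee counts in-bag multiplicity),
#' otherwise every tree sees the full training set and trees differ only
#' through feature subsampling.  Split thresholds are midpoints between
#' adjacent distinct values; rows with `value <= threshold` go left.
#'
#' @param matrix a `feature_matrix` (see [build_feature_matrix()]).
#' @param hp an [rf_hyperparams()] object.
#' @param seed integer seed; fitting is deterministic given it.
#' @param rows optional row indices to train on (e.g. a split's
#'   `train_indices`); defaults to all rows.
#' @param labels optional label override (same length as `rows`), used for
#'   randomized-label null fits.
#' @return An object of class `fitted_forest`: per-tree node tables
#'   (`trees`, columns `nodeID`, `leftChild`, `rightChild`, `splitvarID`,
#'   `splitvarName`, `splitval`, `terminal`, `prediction`, `n_node`), the
#'   normalized impurity importance vector, hyperparameters, feature names
#'   and seed.
#' @export
fit_forest <- function(matrix, hp, seed = 1L, rows = NULL, labels = NULL) {
  stopifnot(inherits(matrix, "feature_matrix"), inherits(hp, "rf_hyperparams"))
  if (is.null(rows)) rows <- seq_len(nrow(matrix$values))
  x <- matrix$values[rows, , drop = FALSE]
  y <- if (is.null(labels)) matrix$labels[rows] else labels
  stopifnot(length(y) == nrow(x))
  if (length(unique(y)) < 2L) {
    stop("training data contain a single class", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  raw <- .grow_forest_cpp(x, as.integer(y), hp$n_estimators,
                          resolve_mtry(hp$max_features, ncol(x)),
                          hp$max_depth, hp$min_samples_leaf, hp$bootstrap)
  imp <- Reduce(`+`, lapply(raw, `[[`, "importance"))
  total <- sum(imp)
  imp <- if (total > 0) imp / total else imp * 0
  names(imp) <- matrix$feature_names
  structure(list(
    cpp_trees = raw,
    trees = lapply(raw, tree_node_table, feature_names = matrix$feature_names),
    importance = imp,
    hyperparams = hp,
    feature_names = matrix$feature_names,
    seed = as.integer(seed),
    n_train = nrow(x)
  ), class = "fitted_forest")
}

#' Forest predictions by majority vote
#'
#' Each tree casts one vote; the positive-class vote share is returned and
#' a participant is classified autistic only when strictly more than half
#' the trees vote so (ties go to the non-autistic class).
#'
#' @param forest a `fitted_forest`.
#' @param values numeric matrix with the forest's feature columns.
#' @return List with `votes` (positive vote share per row) and `class`
#'   (integer predictions, 1 = autistic).
#' @export
predict_forest <- function(forest, values) {
  stopifnot(inherits(forest, "fitted_forest"))
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  votes <- .predict_forest_cpp(forest$cpp_trees, values)
  list(votes = votes, class = as.integer(votes > 0.5))
}

# Train/test performance of one forest under a split.
evaluate_forest <- function(forest, matrix, split) {
  eval_on <- function(rows, role) {
    pred <- predict_forest(forest, matrix$values[rows, , drop = FALSE])
    performance(confusion(matrix$labels[rows], pred$class), split_role = role)
  }
  list(train = eval_on(split$train_indices, "train"),
       test = eval_on(split$test_indices, "test"))
}

# Features used by each tree, as 1-based indices into feature_names.
forest_tree_features <- function(forest) {
  lapply(forest$cpp_trees, function(tree) {
    sort(unique(tree$splitvar[tree$splitvar >= 0L]) + 1L)
  })
}

#' Repeated forest fitting under a fixed split
#'
#' Re-runs the classification procedure `n_repetitions` times with the
#' split held fixed: only the forest-internal randomness (bootstrap
#' resampling and per-split feature subsampling) varies, through per-
#' repetition seeds derived as `seed + repetition`.  With
#' `shuffle_labels = TRUE` the training labels are freshly permuted at each
#' repetition (the randomized-label null forest); evaluation still uses the
#' original labels by default.
#'
#' @param matrix a `feature_matrix`.
#' @param split a `split_spec` from [split_train_test()].
#' @param hp an [rf_hyperparams()] object.
#' @param n_repetitions number of repetitions.
#' @param seed master seed for the repetition sequence.
#' @param shuffle_labels permute training labels each repetition.
#' @param evaluate_on with shuffled labels, evaluate metrics against the
#'   `"original"` labels (default) or the `"shuffled"` ones.
#' @param keep_forests retain every `fitted_forest` (memory-heavy for large
#'   runs; any repetition can be reconstructed exactly with
#'   [refit_repetition()]).
#' @return An object of class `repetition_results`: `metrics` (one row per
#'   repetition: train/test accuracy, sensitivity, specificity, F1),
#'   `importance` (repetitions x features matrix, rows summing to 1),
#'   `tree_features` (per repetition, the feature-index sets of every
#'   tree), plus the settings needed to reproduce any repetition.
#' @export
repeat_fit <- function(matrix, split, hp, n_repetitions = 1000L, seed = 1974L,
                       shuffle_labels = FALSE,
                       evaluate_on = c("original", "shuffled"),
                       keep_forests = FALSE) {
  stopifnot(inherits(matrix, "feature_matrix"), inherits(split, "split_spec"),
            n_repetitions >= 1)
  evaluate_on <- match.arg(evaluate_on)
  p <- length(matrix$feature_names)
  importance <- array(NA_real_, dim = c(n_repetitions, p),
                      dimnames = list(NULL, matrix$feature_names))
  metric_rows <- vector("list", n_repetitions)
  tree_features <- vector("list", n_repetitions)
  forests <- if (keep_forests) vector("list", n_repetitions)

  for (r in seq_len(n_repetitions)) {
    rep_seed <- as.integer(seed + r)
    fit <- fit_one_repetition(matrix, split, hp, rep_seed, shuffle_labels)
    ev_labels <- matrix$labels
    if (shuffle_labels && evaluate_on == "shuffled") {
      ev_labels[split$train_indices] <- fit$train_labels
    }
    eval_matrix <- matrix
    eval_matrix$labels <- ev_labels
    perf <- evaluate_forest(fit$forest, eval_matrix, split)
    metric_rows[[r]] <- c(repetition = r,
                          stats::setNames(performance_row(perf$train),
                                          paste0("train_", names(performance_row(perf$train)))),
                          stats::setNames(performance_row(perf$test),
                                          paste0("test_", names(performance_row(perf$test)))))
    importance[r, ] <- fit$forest$importance
    tree_features[[r]] <- forest_tree_features(fit$forest)
    if (keep_forests) forests[[r]] <- fit$forest
  }
  metrics <- as.data.frame(do.call(rbind, metric_rows))
  structure(list(
    metrics = metrics,
    importance = importance,
    tree_features = tree_features,
    forests = forests,
    hyperparams = hp,
    split = split,
    seed = as.integer(seed),
    shuffle_labels = shuffle_labels,
    evaluate_on = evaluate_on,
    feature_names = matrix$feature_names
  ), class = "repetition_results")
}

# One repetition: derive the (possibly shuffled) training labels and fit.
fit_one_repetition <- function(matrix, split, hp, rep_seed, shuffle_labels) {
  train_labels <- matrix$labels[split$train_indices]
  if (shuffle_labels) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(rep_seed)
    train_labels <- train_labels[sample.int(length(train_labels))]
  }
  forest <- fit_forest(matrix, hp, seed = rep_seed,
                       rows = split$train_indices, labels = train_labels)
  list(forest = forest, train_labels = train_labels)
}

#' Reconstruct the forest of one repetition
#'
#' Repetition seeds are deterministic (`seed + repetition`), so any
#' repetition's forest can be refit bit-identically without having kept it.
#'
#' @param matrix the `feature_matrix` used for the run.
#' @param results a `repetition_results` object.
#' @param repetition repetition index (1-based).
#' @return The `fitted_forest` of that repetition.
#' @export
refit_repetition <- function(matrix, results, repetition) {
  stopifnot(inherits(results, "repetition_results"),
            repetition >= 1, repetition <= nrow(results$metrics))
  fit_one_repetition(matrix, results$split, results$hyperparams,
                     as.integer(results$seed + repetition),
                     results$shuffle_labels)$forest
}

#' Select the best repetition by test F1
#'
#' @param results a `repetition_results` object (or its `metrics` frame).
#' @return The index of the repetition with the highest test-set F1 score;
#'   ties resolve to the lowest index.
#' @export
select_best <- function(results) {
  metrics <- if (inherits(results, "repetition_results")) {
    results$metrics
  } else {
    results
  }
  if (!nrow(metrics)) stop("no repetition results", call. = FALSE)
  which.max(metrics$test_f1)
}

#' Default hyperparameter tuning grid
#'
#' A neighborhood of the settings the analysis ships with: tree count,
#' depth, leaf size and bootstrap are varied, feature subsampling stays at
#' the square-root rule.
#'
#' @return List of [rf_hyperparams()] objects.
#' @export
default_tuning_grid <- function() {
  grid <- expand.grid(n_estimators = c(50L, 100L, 200L),
                      max_depth = 2:5,
                      min_samples_leaf = c(30L, 60L, 90L),
                      bootstrap = c(TRUE, FALSE))
  lapply(seq_len(nrow(grid)), function(i) {
    rf_hyperparams(n_estimators = grid$n_estimators[i],
                   max_features = "sqrt",
                   bootstrap = grid$bootstrap[i],
                   max_depth = grid$max_depth[i],
                   min_samples_leaf = grid$min_samples_leaf[i])
  })
}

#' Grid-search hyperparameter tuning by k-fold cross-validation
#'
#' Evaluates every grid point by k-fold cross-validated F1 (or accuracy)
#' on the training rows and returns the maximizer; ties break toward the
#' simpler model (fewer trees, then shallower).  Per-point training-fold
#' and validation scores are attached so the train/validation gap — the
#' overfitting diagnostic — can be inspected.
#'
#' @param matrix a `feature_matrix` restricted to (or indexed by) the
#'   training rows.
#' @param grid list of [rf_hyperparams()] objects; see
#'   [default_tuning_grid()].
#' @param k_folds number of cross-validation folds.
#' @param seed seed controlling fold assignment and fits.
#' @param rows optional row indices (e.g. a split's `train_indices`).
#' @param metric optimize `"f1"` (default) or `"accuracy"`.
#' @return The winning `rf_hyperparams`, with the per-grid-point score
#'   table in attribute `"cv_results"`.
#' @export
tune_hyperparameters <- function(matrix, grid = default_tuning_grid(),
                                 k_folds = 3L, seed = 1974L, rows = NULL,
                                 metric = c("f1", "accuracy")) {
  stopifnot(inherits(matrix, "feature_matrix"), k_folds >= 2)
  metric <- match.arg(metric)
  if (!length(grid)) stop("empty hyperparameter grid", call. = FALSE)
  if (is.null(rows)) rows <- seq_len(nrow(matrix$values))
  n <- length(rows)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  fold_id <- sample(rep(seq_len(k_folds), length.out = n))

  score_of <- function(report) {
    if (metric == "f1") report$f1 else report$accuracy
  }
  results <- lapply(seq_along(grid), function(i) {
    hp <- grid[[i]]
    val <- train <- numeric(k_folds)
    for (k in seq_len(k_folds)) {
      fit_rows <- rows[fold_id != k]
      hold_rows <- rows[fold_id == k]
      if (length(unique(matrix$labels[hold_rows])) < 2L) {
        warning("fold ", k, " holds a single class; its score may degenerate",
                call. = FALSE)
      }
      forest <- fit_forest(matrix, hp, seed = seed + i * 1000L + k,
                           rows = fit_rows)
      hold_pred <- predict_forest(forest,
                                  matrix$values[hold_rows, , drop = FALSE])
      fit_pred <- predict_forest(forest,
                                 matrix$values[fit_rows, , drop = FALSE])
      val[k] <- score_of(performance(
        confusion(matrix$labels[hold_rows], hold_pred$class)))
      train[k] <- score_of(performance(
        confusion(matrix$labels[fit_rows], fit_pred$class)))
    }
    data.frame(grid_index = i,
               n_estimators = hp$n_estimators,
               max_depth = hp$max_depth,
               min_samples_leaf = hp$min_samples_leaf,
               bootstrap = hp$bootstrap,
               mean_cv_score = mean(val),
               mean_train_score = mean(train),
               train_val_gap = mean(train) - mean(val))
  })
  cv <- do.call(rbind, results)
  ord <- order(-cv$mean_cv_score, cv$n_estimators, cv$max_depth)
  best <- grid[[cv$grid_index[ord[1]]]]
  attr(best, "cv_results") <- cv
  best
}
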