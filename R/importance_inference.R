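# Feature-importance significance against randomized-label null forests.
#
# The inference contrasts two importance distributions per feature: one from
# repeated forests trained on the real diagnosis labels, one from forests
# trained with the training labels freshly permuted at every repetition
# ("random RF"), both under identical hyperparameters and the same fixed
# split.  A per-feature two-tailed Welch t-test with Bonferroni correction
# flags features whose real importance exceeds the null baseline.

#' Importance matrix of randomized-label null forests
#'
#' Convenience wrapper over [repeat_fit()] with `shuffle_labels = TRUE`:
#' at each repetition the training labels are independently permuted, a
#' forest is fitted with the same hyperparameters and split as the real
#' run, and its importance vector extracted.  Performance is still
#' evaluated against the original labels, so the null run doubles as the
#' chance-level baseline for the performance metrics.
#'
#' @inheritParams repeat_fit
#' @return A `repetition_results` object with `shuffle_labels = TRUE`.
#' @export
null_forest_importances <- function(matrix, split, hp, n_repetitions = 1000L,
                                    seed = 1974L,
                                    evaluate_on = c("original", "shuffled")) {
  repeat_fit(matrix, split, hp, n_repetitions = n_repetitions, seed = seed,
             shuffle_labels = TRUE, evaluate_on = match.arg(evaluate_on))
}

# Welch (or pooled) two-sample t-test returning c(t, p); degenerate
# zero-variance columns with equal means give t = 0, p = 1.
two_sample_t <- function(x, y, var_equal = FALSE) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) return(c(t = 0, p = 1))
    return(c(t = sign(mean(x) - mean(y)) * Inf, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  c(t = unname(ht$statistic), p = ht$p.value)
}

#' Test feature-importance significance against the null forests
#'
#' Per feature, a two-tailed independent-samples t-test (Welch by default)
#' compares the importance distribution of the real-label forests with that
#' of the randomized-label forests; p-values are Bonferroni-corrected over
#' all features.  A feature is flagged significant only when its corrected
#' p-value is below `alpha` *and* its mean real importance exceeds the null
#' mean — the two-tailed p is reported alongside the directional flag
#' rather than folding the direction into the test.
#'
#' Because the real-label run holds one fixed labeling across repetitions,
#' the t-test treats as evidence any chance association between a feature
#' and that particular labeling; it therefore does not control the
#' dataset-level false-positive rate (see the methods vignette).
#' `method = "permutation"` instead computes a one-sided empirical p-value
#' of the mean real importance against the null run's importance
#' distribution (`(1 + #\{null >= mean real\}) / (R_null + 1)`), which is
#' calibrated at the dataset level.
#'
#' @param real,null repetition x feature importance matrices (or
#'   `repetition_results` objects) sharing feature columns, each with at
#'   least two rows.
#' @param alpha significance level (after correction).
#' @param method `"ttest"` (default, the repeated-fit t-test) or
#'   `"permutation"` (empirical p against the null distribution).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return An object of class `importance_inference`: a `data.frame` with
#'   `feature`, `mean_real`, `mean_null`, `t_stat` (`NA` for the
#'   permutation method), `p_raw`, `p_bonferroni` and `significant`, with
#'   `alpha` and `method` as attributes.
#' @export
test_significance <- function(real, null, alpha = 0.05,
                              method = c("ttest", "permutation"),
                              var_equal = FALSE) {
  method <- match.arg(method)
  get_imp <- function(x) {
    if (inherits(x, "repetition_results")) x$importance else as.matrix(x)
  }
  real_m <- get_imp(real)
  null_m <- get_imp(null)
  if (!identical(colnames(real_m), colnames(null_m))) {
    stop("real and null importance matrices must share feature columns",
         call. = FALSE)
  }
  stopifnot(nrow(real_m) >= 2, nrow(null_m) >= 2, alpha >= 0, alpha <= 1)
  p <- ncol(real_m)
  mean_real <- colMeans(real_m)
  mean_null <- colMeans(null_m)
  if (method == "ttest") {
    tests <- vapply(seq_len(p), function(j) {
      two_sample_t(real_m[, j], null_m[, j], var_equal = var_equal)
    }, numeric(2))
    t_stat <- unname(tests["t", ])
    p_raw <- unname(tests["p", ])
  } else {
    t_stat <- rep(NA_real_, p)
    r_null <- nrow(null_m)
    p_raw <- vapply(seq_len(p), function(j) {
      (1 + sum(null_m[, j] >= mean_real[j])) / (r_null + 1)
    }, numeric(1))
  }
  p_bonf <- pmin(1, p_raw * p)
  out <- data.frame(
    feature = colnames(real_m),
    mean_real = unname(mean_real),
    mean_null = unname(mean_null),
    t_stat = t_stat,
    p_raw = p_raw,
    p_bonferroni = p_bonf,
    significant = unname(p_bonf < alpha & mean_real > mean_null),
    stringsAsFactors = FALSE
  )
  structure(out, alpha = alpha, method = method,
            class = c("importance_inference", "data.frame"))
}

#' Partial dependence of the forest on one feature
#'
#' For each grid value, the chosen feature is clamped to that value in
#' every training row while all other features keep their observed joint
#' distribution, and the forest's positive-class vote share is averaged
#' over rows.
#'
#' @param forest a `fitted_forest`.
#' @param feature feature name.
#' @param data numeric matrix of background rows (typically the training
#'   rows of the feature matrix).
#' @param grid numeric grid of clamp values; defaults to 20 quantiles of
#'   the feature in `data`.
#' @return A `data.frame` with `grid` and `mean_prediction` (mean positive
#'   vote share).
#' @export
partial_dependence <- function(forest, feature, data, grid = NULL) {
  stopifnot(inherits(forest, "fitted_forest"))
  if (!feature %in% forest$feature_names) {
    stop("unknown feature '", feature, "'", call. = FALSE)
  }
  if (is.null(grid)) {
    grid <- unname(stats::quantile(data[, feature],
                                   probs = seq(0.025, 0.975, length.out = 20)))
  }
  if (!length(grid)) stop("empty partial-dependence grid", call. = FALSE)
  mean_pred <- vapply(grid, function(g) {
    clamped <- data
    clamped[, feature] <- g
    mean(predict_forest(forest, clamped)$votes)
  }, numeric(1))
  data.frame(grid = grid, mean_prediction = mean_pred)
}
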