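# AQ-28 threshold classifier and the combined (tasks + questionnaire)
# model.  The questionnaire classifies a participant as autistic when the
# AQ-28 total meets or exceeds a threshold; sweeping the threshold over the
# instrument's integer range 28..112 traces the accuracy / sensitivity /
# specificity trade-off.  The combined model appends the AQ total as one
# extra feature and re-runs the repeated-forest procedure with the
# hyperparameters frozen, so any performance change is attributable to the
# feature set alone.

#' Classify by AQ-28 threshold
#'
#' @param records cohort data frame with `aq_total` present for all rows.
#' @param threshold AQ total cut-off; scores `>= threshold` classify as
#'   autistic.
#' @return Integer predictions (1 = autistic).
#' @export
aq_classify <- function(records, threshold) {
  aq <- records$aq_total
  if (anyNA(aq)) {
    stop("missing AQ total for participant(s): ",
         paste(records$participant_id[is.na(aq)], collapse = ", "),
         call. = FALSE)
  }
  as.integer(aq >= threshold)
}

#' Threshold sweep of the AQ-28 classifier
#'
#' Evaluates the `>=`-rule classifier at every threshold.  By construction
#' sensitivity is non-increasing and specificity non-decreasing as the
#' threshold rises.  The best threshold by accuracy is reported (ties to
#' the lowest threshold).
#'
#' @param records cohort data frame with `aq_total` and `group`.
#' @param thresholds ordered thresholds; default the full integer AQ-28
#'   range 28..112.
#' @return An object of class `aq_sweep`: `data.frame` with `threshold`,
#'   `accuracy`, `sensitivity`, `specificity`, `f1`, and the winning
#'   threshold in attribute `"best_threshold_by_accuracy"`.
#' @export
aq_sweep <- function(records, thresholds = 28:112) {
  if (!length(thresholds)) stop("empty threshold range", call. = FALSE)
  labels <- as.integer(records$group == "autistic")
  rows <- lapply(thresholds, function(th) {
    rep <- suppressWarnings(
      performance(confusion(labels, aq_classify(records, th))))
    data.frame(threshold = th, accuracy = rep$accuracy,
               sensitivity = rep$sensitivity, specificity = rep$specificity,
               f1 = rep$f1)
  })
  out <- do.call(rbind, rows)
  best <- out$threshold[which.max(out$accuracy)]
  structure(out, best_threshold_by_accuracy = best,
            class = c("aq_sweep", "data.frame"))
}

#' Combined task-battery + AQ-28 forest model
#'
#' Appends the AQ-28 total as an additional feature (refusing a second AQ
#' column) and re-runs the repeated-forest procedure with the supplied
#' hyperparameters unchanged, so improvements cannot be assigned to model
#' differences.  With `aq_totals = NULL` the identical code path runs on
#' the unaugmented matrix, which is the control for attributing changes to
#' the feature set.
#'
#' @param matrix the objective-measures `feature_matrix`.
#' @param aq_totals AQ-28 totals, one per row, or `NULL` to withhold AQ.
#' @param hp_frozen the hyperparameters of the objective-only run, reused
#'   verbatim.
#' @param split the same `split_spec` as the objective-only run.
#' @param n_repetitions,seed as in [repeat_fit()].
#' @return List with the augmented `feature_matrix`, the
#'   `repetition_results`, `best_index` and the best repetition's test
#'   metrics row.
#' @export
combined_model <- function(matrix, aq_totals, hp_frozen, split,
                           n_repetitions = 1000L, seed = 1974L) {
  stopifnot(inherits(hp_frozen, "rf_hyperparams"))
  augmented <- if (is.null(aq_totals)) {
    matrix
  } else {
    append_aq(matrix, aq_totals)
  }
  results <- repeat_fit(augmented, split, hp_frozen,
                        n_repetitions = n_repetitions, seed = seed)
  best <- select_best(results)
  list(feature_matrix = augmented,
       results = results,
       best_index = best,
       best_metrics = results$metrics[best, , drop = FALSE])
}

#' Compare objective-only, AQ-only and combined classifiers
#'
#' Runs the repeated-forest procedure on the objective features alone and
#' with the AQ-28 appended (same split, seed and frozen hyperparameters),
#' plus the AQ threshold sweep, and tabulates best-model test metrics for
#' the three sources.  The AQ-alone metrics are computed on the full group
#' by default (`aq_on = "all"`), or on the test split only.
#'
#' @param records complete cohort data frame.
#' @param hp frozen [rf_hyperparams()].
#' @param split a `split_spec` for the forest runs.
#' @param n_repetitions,seed as in [repeat_fit()].
#' @param aq_on evaluate the AQ sweep on `"all"` records or `"test"` rows.
#' @return List with `comparison` (one metrics row per source), the two
#'   `repetition_results`, and the `aq_sweep`.
#' @export
compare_sources <- function(records, hp, split, n_repetitions = 100L,
                            seed = 1974L, aq_on = c("all", "test")) {
  aq_on <- match.arg(aq_on)
  fm <- build_feature_matrix(records)
  objective <- combined_model(fm, NULL, hp, split,
                              n_repetitions = n_repetitions, seed = seed)
  combined <- combined_model(fm, records$aq_total, hp, split,
                             n_repetitions = n_repetitions, seed = seed)
  sweep_records <- if (aq_on == "all") {
    records
  } else {
    records[split$test_indices, , drop = FALSE]
  }
  sweep <- aq_sweep(sweep_records)
  best_th <- attr(sweep, "best_threshold_by_accuracy")
  aq_row <- sweep[sweep$threshold == best_th, , drop = FALSE]

  pick <- function(m) {
    data.frame(accuracy = m$test_accuracy, sensitivity = m$test_sensitivity,
               specificity = m$test_specificity, f1 = m$test_f1)
  }
  comparison <- rbind(
    cbind(source = "objective_only", pick(objective$best_metrics)),
    cbind(source = "aq_only",
          data.frame(accuracy = aq_row$accuracy,
                     sensitivity = aq_row$sensitivity,
                     specificity = aq_row$specificity, f1 = aq_row$f1)),
    cbind(source = "combined", pick(combined$best_metrics))
  )
  list(comparison = comparison,
       objective = objective,
       combined = combined,
       aq_sweep = sweep,
       aq_best_threshold = best_th)
}
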