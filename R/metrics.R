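# Confusion-matrix bookkeeping and the four reported performance metrics.
# The positive class is "autistic" throughout: TP counts autistic
# participants correctly classified as autistic, TN non-autistic ones
# correctly classified as non-autistic.

#' Confusion counts for binary predictions
#'
#' @param labels true labels, binary (1 = autistic, 0 = non-autistic).
#' @param predictions predicted labels, same coding and length.
#' @return An object of class `confusion_counts`: list with integer
#'   `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) == 0L) stop("empty label vector", call. = FALSE)
  if (length(labels) != length(predictions)) {
    stop("labels and predictions differ in length", call. = FALSE)
  }
  labels <- as.integer(labels)
  predictions <- as.integer(predictions)
  if (!all(labels %in% c(0L, 1L)) || !all(predictions %in% c(0L, 1L))) {
    stop("labels and predictions must be binary 0/1", call. = FALSE)
  }
  structure(list(
    tp = sum(labels == 1L & predictions == 1L),
    tn = sum(labels == 0L & predictions == 0L),
    fp = sum(labels == 0L & predictions == 1L),
    fn = sum(labels == 1L & predictions == 0L)
  ), class = "confusion_counts")
}

#' Performance metrics from confusion counts
#'
#' Computes accuracy `(TP + TN) / (TP + FP + FN + TN)`, sensitivity
#' `TP / (TP + FN)`, specificity `TN / (TN + FP)` and F1 score
#' `2 TP / (2 TP + FP + FN)`.  A zero denominator (degenerate evaluation
#' set) yields 0 for that metric with a warning, so large repeated-fitting
#' runs fail loudly but keep going.
#'
#' @param counts a `confusion_counts` object.
#' @param split_role optional tag, `"train"` or `"test"`.
#' @return An object of class `performance_report`: list with `accuracy`,
#'   `sensitivity`, `specificity`, `f1`, the `counts` and `split_role`.
#' @export
performance <- function(counts, split_role = NA_character_) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total == 0L) stop("empty confusion table", call. = FALSE)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator for ", what, "; reporting 0", call. = FALSE)
      return(0)
    }
    num / den
  }
  structure(list(
    accuracy = (counts$tp + counts$tn) / total,
    sensitivity = safe_div(counts$tp, counts$tp + counts$fn, "sensitivity"),
    specificity = safe_div(counts$tn, counts$tn + counts$fp, "specificity"),
    f1 = safe_div(2 * counts$tp, 2 * counts$tp + counts$fp + counts$fn, "F1"),
    counts = counts,
    split_role = split_role
  ), class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.3f | sensitivity %.3f | specificity %.3f | F1 %.3f%s\n",
    x$accuracy, x$sensitivity, x$specificity, x$f1,
    if (is.na(x$split_role)) "" else paste0(" [", x$split_role, "]")))
  invisible(x)
}

# Flat numeric view used when tabulating repetition results.
performance_row <- function(report) {
  c(accuracy = report$accuracy, sensitivity = report$sensitivity,
    specificity = report$specificity, f1 = report$f1)
}
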