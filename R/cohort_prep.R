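# Cohort preparation: exclusion of incomplete records, age/gender-matched
# subsample construction, feature-matrix assembly and the train/test split.

#' Exclude records with missing task data
#'
#' Drops every participant with at least one missing task-feature value
#' (missingness is block-structured in generated cohorts: a record is either
#' complete or missing a whole task block).  Row order is preserved and the
#' number of exclusions is reported.
#'
#' @param records cohort data frame.
#' @return The complete records, same class and attributes.
#' @export
exclude_incomplete <- function(records) {
  feats <- cohort_feature_names(records)
  complete <- stats::complete.cases(records[, feats, drop = FALSE])
  n_excluded <- sum(!complete)
  message(n_excluded, " of ", nrow(records),
          " participants excluded for missing task data; ",
          sum(complete), " remain")
  if (!any(complete)) {
    warning("no complete records remain after exclusion", call. = FALSE)
  }
  out <- records[complete, , drop = FALSE]
  attr(out, "task_blocks") <- attr(records, "task_blocks")
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Build an age- and gender-matched subsample
#'
#' Constructs one-to-one autistic/non-autistic pairs with identical gender
#' and identical age (in whole years, up to `age_tolerance`), selected by a
#' randomized greedy bipartite matching: autistic records are visited in
#' random order and each is paired with a uniformly drawn unused feasible
#' counterpart.  By construction the two matched groups have equal size and
#' identical gender tallies.
#'
#' @param records cohort data frame with both groups present.
#' @param seed integer seed for the randomized matching.
#' @param age_tolerance maximum difference in rounded age, in whole years;
#'   the default 0 requires the same integer year.
#' @param target_size optional number of pairs; fewer feasible pairs than
#'   requested is a warning, more are discarded at random.
#' @return Matched cohort (pairs stacked, autistic rows first), with the
#'   number of pairs in attribute `"n_pairs"`.
#' @export
match_age_gender <- function(records, seed = 1L, age_tolerance = 0,
                             target_size = NULL) {
  stopifnot(all(c("group", "age", "gender") %in% names(records)))
  aut <- which(records$group == "autistic")
  ctl <- which(records$group == "nonautistic")
  if (!length(aut) || !length(ctl)) {
    stop("both groups must be present for matching", call. = FALSE)
  }
  age_i <- round(records$age)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  order_aut <- sample(aut)
  used <- logical(nrow(records))
  pairs <- matrix(integer(0), ncol = 2)
  for (a in order_aut) {
    feasible <- ctl[!used[ctl] &
                      records$gender[ctl] == records$gender[a] &
                      abs(age_i[ctl] - age_i[a]) <= age_tolerance]
    if (!length(feasible)) next
    b <- if (length(feasible) == 1L) feasible else sample(feasible, 1L)
    used[b] <- TRUE
    pairs <- rbind(pairs, c(a, b))
    if (!is.null(target_size) && nrow(pairs) >= target_size) break
  }
  if (!nrow(pairs)) {
    stop("no feasible age/gender-matched pairs between the groups",
         call. = FALSE)
  }
  if (!is.null(target_size) && nrow(pairs) < target_size) {
    warning("only ", nrow(pairs), " feasible pairs found (",
            target_size, " requested)", call. = FALSE)
  }
  message(nrow(pairs), " matched pairs constructed")
  out <- records[c(pairs[, 1], pairs[, 2]), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "task_blocks") <- attr(records, "task_blocks")
  attr(out, "n_pairs") <- nrow(pairs)
  out
}

#' Assemble the classifier feature matrix
#'
#' Binds the 54 task features with age and gender (encoded 1 = woman,
#' 0 = man) into the 56-column input the classifier consumes; the AQ-28
#' total can be appended as a 57th column for the combined model.  Features
#' are used unscaled: tree ensembles are invariant to monotone rescaling of
#' inputs, so no normalization is applied.
#'
#' @param records complete cohort data frame (no missing task values).
#' @param include_age_gender append `age` and `gender` columns (default).
#' @param include_aq append the `aq_total` column.
#' @return An object of class `feature_matrix`: list with `values`
#'   (numeric matrix), `feature_names`, `labels` (integer, 1 = autistic)
#'   and `participant_ids`.
#' @export
build_feature_matrix <- function(records, include_age_gender = TRUE,
                                 include_aq = FALSE) {
  feats <- cohort_feature_names(records)
  x <- as.matrix(records[, feats, drop = FALSE])
  storage.mode(x) <- "double"
  if (anyNA(x)) {
    stop("feature matrix requires complete records; run exclude_incomplete()",
         call. = FALSE)
  }
  if (include_age_gender) {
    x <- cbind(x, age = records$age,
               gender = as.numeric(records$gender == "w"))
  }
  if (include_aq) {
    if ("aq_total" %in% colnames(x)) {
      stop("AQ column already present in the feature matrix", call. = FALSE)
    }
    x <- cbind(x, aq_total = records$aq_total)
  }
  structure(list(
    values = x,
    feature_names = colnames(x),
    labels = as.integer(records$group == "autistic"),
    participant_ids = as.character(records$participant_id)
  ), class = "feature_matrix")
}

#' Append a questionnaire total to an existing feature matrix
#'
#' @param matrix a `feature_matrix`.
#' @param aq_totals numeric vector, one value per row of the matrix.
#' @return The augmented `feature_matrix` (one extra `aq_total` column).
#' @export
append_aq <- function(matrix, aq_totals) {
  stopifnot(inherits(matrix, "feature_matrix"),
            length(aq_totals) == nrow(matrix$values))
  if ("aq_total" %in% matrix$feature_names) {
    stop("AQ column already present in the feature matrix", call. = FALSE)
  }
  matrix$values <- cbind(matrix$values, aq_total = as.numeric(aq_totals))
  matrix$feature_names <- colnames(matrix$values)
  matrix
}

#' Split a feature matrix into train and test sets
#'
#' The test set holds `round(n * (1 - train_fraction))` rows (clamped so
#' both sets are non-empty), drawn uniformly at random given `seed`; with
#' n = 552 and an 80/20 split this yields 442/110, and with n = 250 it
#' yields 200/50.
#'
#' @param matrix a `feature_matrix` (or anything with a row count via `n`).
#' @param train_fraction proportion of rows assigned to training.
#' @param seed integer seed.
#' @param n row count, derived from `matrix` when supplied.
#' @return An object of class `split_spec`: list with disjoint
#'   `train_indices` and `test_indices` covering all rows, plus
#'   `train_fraction` and `seed`.
#' @export
split_train_test <- function(matrix = NULL, train_fraction = 0.8, seed = 1974L,
                             n = NULL) {
  if (is.null(n)) {
    stopifnot(inherits(matrix, "feature_matrix"))
    n <- nrow(matrix$values)
  }
  if (n < 2) stop("need at least 2 rows to split", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  n_test <- round(n * (1 - train_fraction))
  n_test <- max(1L, min(n - 1L, as.integer(n_test)))

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  test_idx <- sort(sample.int(n, n_test))
  structure(list(
    train_indices = setdiff(seq_len(n), test_idx),
    test_indices = test_idx,
    train_fraction = train_fraction,
    seed = as.integer(seed)
  ), class = "split_spec")
}

#' Write / read a split specification as JSON
#'
#' @param split a `split_spec`.
#' @param path JSON file path.
#' @return `path` invisibly for the writer; a `split_spec` for the reader.
#' @export
write_split <- function(split, path) {
  stopifnot(inherits(split, "split_spec"))
  jsonlite::write_json(unclass(split), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    train_indices = as.integer(x$train_indices),
    test_indices = as.integer(x$test_indices),
    train_fraction = x$train_fraction,
    seed = as.integer(x$seed)
  ), class = "split_spec")
}

#' Per-group demographic summary with rank-sum tests
#'
#' Summarizes age, gender composition, ICAR and AQ-28 total per group as
#' mean (SD) or counts, with a two-sided Mann-Whitney U test per row
#' (gender is tested on its binary coding) and a flag at p < 0.001.
#'
#' @param records cohort data frame with at least two records per group.
#' @param flag_alpha flag threshold on the U-test p-value.
#' @return A `data.frame` with one row per variable: group summaries,
#'   `p_value` and `significant`.
#' @export
cohort_summary <- function(records, flag_alpha = 0.001) {
  g <- records$group
  if (min(table(g)) < 2) {
    stop("need at least two records per group", call. = FALSE)
  }
  aut <- records[g == "autistic", , drop = FALSE]
  ctl <- records[g == "nonautistic", , drop = FALSE]

  utest <- function(x, y) {
    if (stats::sd(c(x, y)) == 0) {
      warning("constant column in group summary; p set to 1", call. = FALSE)
      return(1)
    }
    stats::wilcox.test(x, y, exact = FALSE)$p.value
  }
  msd <- function(x) sprintf("%.1f(%.1f)", mean(x), stats::sd(x))

  rows <- list(
    age = list(msd(aut$age), msd(ctl$age), utest(aut$age, ctl$age)),
    gender = list(
      sprintf("%d/%d(%.1f)", sum(aut$gender == "w"), sum(aut$gender == "m"),
              100 * mean(aut$gender == "w")),
      sprintf("%d/%d(%.1f)", sum(ctl$gender == "w"), sum(ctl$gender == "m"),
              100 * mean(ctl$gender == "w")),
      utest(as.numeric(aut$gender == "w"), as.numeric(ctl$gender == "w"))),
    icar = list(sprintf("%.2f(%.2f)", mean(aut$icar), stats::sd(aut$icar)),
                sprintf("%.2f(%.2f)", mean(ctl$icar), stats::sd(ctl$icar)),
                utest(aut$icar, ctl$icar)),
    aq_total = list(msd(aut$aq_total), msd(ctl$aq_total),
                    utest(aut$aq_total, ctl$aq_total))
  )
  data.frame(
    variable = names(rows),
    autistic = vapply(rows, function(r) r[[1]], character(1)),
    nonautistic = vapply(rows, function(r) r[[2]], character(1)),
    p_value = vapply(rows, function(r) r[[3]], numeric(1)),
    significant = vapply(rows, function(r) r[[3]] < flag_alpha, logical(1)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
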