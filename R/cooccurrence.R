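# Feature co-occurrence within decision trees: for every tree in an
# ensemble, every unordered pair of distinct features used by that tree's
# internal nodes counts once; the pair counts over all trees are normalized
# so the whole matrix sums to one.  Diagonal cells (a feature with itself)
# are excluded.  These are not correlation matrices: a high weight only says
# the two features are frequently used together in one tree's decision
# logic.

#' Features used by one decision tree
#'
#' @param tree a per-tree node table as stored in a `fitted_forest`'s
#'   `trees` list (columns `terminal` and `splitvarName`).
#' @return Character vector of the distinct features split on anywhere in
#'   the tree; empty for a single-leaf tree.
#' @export
features_in_tree <- function(tree) {
  if (!is.data.frame(tree) ||
      !all(c("terminal", "splitvarName") %in% names(tree))) {
    stop("malformed tree node table", call. = FALSE)
  }
  unique(tree$splitvarName[!tree$terminal])
}

# Accept fitted forests, repetition results, or raw per-tree feature sets.
collect_tree_feature_sets <- function(x, feature_names = NULL) {
  if (inherits(x, "fitted_forest")) {
    return(list(sets = lapply(x$trees, features_in_tree),
                feature_names = x$feature_names))
  }
  if (inherits(x, "repetition_results")) {
    sets <- lapply(unlist(x$tree_features, recursive = FALSE),
                   function(idx) x$feature_names[idx])
    return(list(sets = sets, feature_names = x$feature_names))
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "fitted_forest"))) {
    sets <- unlist(lapply(x, function(f) lapply(f$trees, features_in_tree)),
                   recursive = FALSE)
    return(list(sets = sets, feature_names = x[[1]]$feature_names))
  }
  stop("cannot extract trees from this object", call. = FALSE)
}

#' Feature co-occurrence likelihood matrix
#'
#' Counts, over every decision tree in the supplied ensemble(s), each
#' unordered pair of distinct features appearing together in that tree
#' (presence, not node multiplicity), then divides by the grand total so
#' all entries sum to one.  With `multiplicity = TRUE` a pair instead
#' contributes the product of the two features' node counts in the tree.
#'
#' @param x a `fitted_forest`, a list of them, or a `repetition_results`
#'   object (whose per-tree feature sets cover all repetitions).
#' @param multiplicity weight pairs by node-count products instead of
#'   presence (presence counting is required for the sum-to-one reading of
#'   the default).
#' @return An object of class `cooccurrence_matrix`: list with `weights`
#'   (symmetric features x features matrix of proportions, zero diagonal),
#'   `feature_names` and `n_trees_counted`.
#' @export
cooccurrence <- function(x, multiplicity = FALSE) {
  if (multiplicity) {
    collected <- collect_tree_multisets(x)
  } else {
    collected <- collect_tree_feature_sets(x)
  }
  feats <- collected$feature_names
  p <- length(feats)
  w <- array(0, dim = c(p, p), dimnames = list(feats, feats))
  if (multiplicity) {
    for (counts in collected$sets) {
      nm <- names(counts)
      if (length(nm) < 2L) next
      idx <- match(nm, feats)
      for (a in seq_along(idx)[-length(idx)]) {
        for (b in seq((a + 1), length(idx))) {
          add <- counts[[a]] * counts[[b]]
          w[idx[a], idx[b]] <- w[idx[a], idx[b]] + add
          w[idx[b], idx[a]] <- w[idx[b], idx[a]] + add
        }
      }
    }
  } else {
    for (set in collected$sets) {
      if (length(set) < 2L) next
      idx <- match(set, feats)
      for (a in seq_along(idx)[-length(idx)]) {
        for (b in seq((a + 1), length(idx))) {
          w[idx[a], idx[b]] <- w[idx[a], idx[b]] + 1
          w[idx[b], idx[a]] <- w[idx[b], idx[a]] + 1
        }
      }
    }
  }
  total <- sum(w[upper.tri(w)])
  if (total == 0) {
    stop("no co-occurrences: no tree uses two or more distinct features",
         call. = FALSE)
  }
  # normalize so the counted (unordered) pairs sum to 1; each pair's weight
  # is mirrored across the diagonal for symmetric presentation
  w <- w / total
  structure(list(weights = w, feature_names = feats,
                 n_trees_counted = length(collected$sets)),
            class = "cooccurrence_matrix")
}

# Node-count multisets per tree, for the multiplicity-weighted mode.
collect_tree_multisets <- function(x) {
  if (inherits(x, "fitted_forest")) x <- list(x)
  if (!(is.list(x) && all(vapply(x, inherits, logical(1), "fitted_forest")))) {
    stop("multiplicity mode needs fitted forests (node tables)", call. = FALSE)
  }
  sets <- unlist(lapply(x, function(f) {
    lapply(f$trees, function(tree) {
      tab <- table(tree$splitvarName[!tree$terminal])
      stats::setNames(as.numeric(tab), names(tab))
    })
  }), recursive = FALSE)
  list(sets = sets, feature_names = x[[1]]$feature_names)
}

#' Total counted weight of a co-occurrence matrix
#'
#' Sums each unordered pair once (the normalization target is exactly 1).
#'
#' @param cm a `cooccurrence_matrix`.
#' @return Numeric scalar.
#' @export
cooccurrence_total <- function(cm) {
  stopifnot(inherits(cm, "cooccurrence_matrix"))
  sum(cm$weights[upper.tri(cm$weights)])
}

#' Contrast real-label and null-label co-occurrence structure
#'
#' @param real,null ensembles (see [cooccurrence()]) fitted on real and on
#'   randomized labels.
#' @param multiplicity passed through to [cooccurrence()].
#' @return List with the two normalized `cooccurrence_matrix` objects and
#'   their `difference` (real minus null weights).
#' @export
cooccurrence_null_contrast <- function(real, null, multiplicity = FALSE) {
  cm_real <- cooccurrence(real, multiplicity = multiplicity)
  cm_null <- cooccurrence(null, multiplicity = multiplicity)
  list(real = cm_real, null = cm_null,
       difference = cm_real$weights - cm_null$weights)
}

#' Write a co-occurrence matrix as CSV
#'
#' @param cm a `cooccurrence_matrix`.
#' @param path output path; feature names form the header row and first
#'   column.
#' @return `path`, invisibly.
#' @export
write_cooccurrence <- function(cm, path) {
  stopifnot(inherits(cm, "cooccurrence_matrix"))
  utils::write.csv(as.data.frame(cm$weights), path, row.names = TRUE)
  invisible(path)
}
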