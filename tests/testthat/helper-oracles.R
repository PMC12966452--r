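# Shared fixtures and independent brute-force oracles used across tests.
# The oracles deliberately re-derive quantities from the per-tree node
# tables with naive enumeration, independent of the package's compiled
# paths.

# A small iid-Gaussian feature matrix with balanced labels; `signal` adds a
# group mean shift on the first feature.
tiny_feature_matrix <- function(n = 200, p = 6, seed = 1, signal = 0) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), length.out = n)
  values <- matrix(rnorm(n * p), n, p,
                   dimnames = list(NULL, paste0("f", seq_len(p))))
  values[, 1] <- values[, 1] + signal * labels
  structure(list(values = values, feature_names = colnames(values),
                 labels = labels,
                 participant_ids = sprintf("T%03d", seq_len(n))),
            class = "feature_matrix")
}

# Follow one row down one node table.
traverse_tree <- function(tree, x) {
  node <- 1L
  while (!tree$terminal[node]) {
    node <- if (x[[tree$splitvarName[node]]] <= tree$splitval[node]) {
      tree$leftChild[node] + 1L
    } else {
      tree$rightChild[node] + 1L
    }
  }
  tree$prediction[node]
}

# Positive vote share by naive per-tree, per-row traversal.
oracle_votes <- function(forest, values) {
  vapply(seq_len(nrow(values)), function(i) {
    mean(vapply(forest$trees, traverse_tree, numeric(1),
                x = values[i, ]))
  }, numeric(1))
}

# Brute-force co-occurrence: enumerate every unordered feature pair of
# every tree directly from the node tables.
oracle_cooccurrence <- function(forests) {
  if (inherits(forests, "fitted_forest")) forests <- list(forests)
  feats <- forests[[1]]$feature_names
  counts <- matrix(0, length(feats), length(feats),
                   dimnames = list(feats, feats))
  for (f in forests) {
    for (tree in f$trees) {
      used <- sort(unique(tree$splitvarName[!tree$terminal]))
      if (length(used) < 2) next
      for (a in seq_along(used)) {
        for (b in seq_along(used)) {
          if (a < b) {
            counts[used[a], used[b]] <- counts[used[a], used[b]] + 1
            counts[used[b], used[a]] <- counts[used[b], used[a]] + 1
          }
        }
      }
    }
  }
  counts / sum(counts[upper.tri(counts)])
}

# Clamp-and-average partial dependence via naive traversal.
oracle_partial_dependence <- function(forest, feature, data, grid) {
  vapply(grid, function(g) {
    clamped <- data
    clamped[, feature] <- g
    mean(oracle_votes(forest, clamped))
  }, numeric(1))
}

# Build a minimal fitted_forest whose trees use exactly the given feature
# sets (each set becomes one chain-shaped tree), for co-occurrence tests.
fake_forest <- function(sets, feature_names) {
  trees <- lapply(sets, function(set) {
    k <- length(set)
    if (k == 0) {
      return(data.frame(nodeID = 0L, leftChild = NA_integer_,
                        rightChild = NA_integer_, splitvarID = NA_integer_,
                        splitvarName = NA_character_, splitval = NA_real_,
                        terminal = TRUE, prediction = 0L, n_node = 10L,
                        stringsAsFactors = FALSE))
    }
    # chain: node i splits on set[i]; left child is a leaf, right child the
    # next split (last right child is a leaf)
    n_nodes <- 2L * k + 1L
    tab <- data.frame(nodeID = seq_len(n_nodes) - 1L,
                      leftChild = NA_integer_, rightChild = NA_integer_,
                      splitvarID = NA_integer_,
                      splitvarName = NA_character_, splitval = NA_real_,
                      terminal = TRUE, prediction = 0L, n_node = 10L,
                      stringsAsFactors = FALSE)
    for (i in seq_len(k)) {
      row <- 2L * (i - 1L) + 1L
      tab$terminal[row] <- FALSE
      tab$splitvarName[row] <- set[i]
      tab$splitvarID[row] <- match(set[i], feature_names) - 1L
      tab$splitval[row] <- 0
      tab$leftChild[row] <- row        # 0-based id of next row
      tab$rightChild[row] <- row + 1L
    }
    tab
  })
  structure(list(trees = trees, feature_names = feature_names),
            class = "fitted_forest")
}

# No-signal generator configuration: identical groups everywhere.
null_synthetic_config <- function(seed, n = 125L) {
  cfg <- synthetic_config(
    seed = seed, n_autistic = n, n_nonautistic = n,
    joint_signal_specs = list(),
    age_params = list(autistic = c(mean = 38, sd = 13),
                      nonautistic = c(mean = 38, sd = 13)),
    gender_women_share = c(autistic = 0.6, nonautistic = 0.6),
    aq_params = list(autistic = c(mean = 70, sd = 12),
                     nonautistic = c(mean = 70, sd = 12)),
    icar_params = list(autistic = c(mean = 0.54, sd = 0.2),
                       nonautistic = c(mean = 0.54, sd = 0.2)))
  cfg$effect_sizes[] <- 0
  cfg
}

# Standardized group mean difference of one cohort column.
cohens_d_hat <- function(records, feature) {
  a <- records[[feature]][records$group == "autistic"]
  b <- records[[feature]][records$group == "nonautistic"]
  (mean(a) - mean(b)) / sqrt(((length(a) - 1) * var(a) +
                                (length(b) - 1) * var(b)) /
                               (length(a) + length(b) - 2))
}

# Feature matrix built directly from two cohort columns.
pair_feature_matrix <- function(records, features) {
  structure(list(
    values = as.matrix(records[, features, drop = FALSE]),
    feature_names = features,
    labels = as.integer(records$group == "autistic"),
    participant_ids = as.character(records$participant_id)
  ), class = "feature_matrix")
}
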