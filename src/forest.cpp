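// Native random-forest engine: CART trees with the Gini criterion,
// per-split feature subsampling (mtry), optional bootstrap resampling,
// a hard depth limit and a hard minimum leaf size.  The leaf-size
// constraint is enforced on the in-bag sample (bootstrap multiplicity
// counts), matching the convention of the reference toolkit the analysis
// mirrors.  All randomness goes through R's RNG so fits are reproducible
// from set.seed() on the R side.

#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Node {
  int left = -1;        // child node ids, -1 for leaves
  int right = -1;
  int splitvar = -1;    // 0-based feature index, -1 for leaves
  double splitval = NA_REAL;
  int pred = 0;         // majority class at the node (ties -> 0)
  int n_node = 0;       // in-bag rows reaching the node
  int n_pos = 0;
};

inline double gini(double n_pos, double n) {
  if (n <= 0.0) return 0.0;
  double p = n_pos / n;
  return 2.0 * p * (1.0 - p);
}

// Draw k of n indices without replacement (partial Fisher-Yates, R RNG).
std::vector<int> sample_features(int n, int k) {
  std::vector<int> pool(n);
  for (int i = 0; i < n; ++i) pool[i] = i;
  for (int i = 0; i < k; ++i) {
    int j = i + static_cast<int>(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(pool[i], pool[j]);
  }
  pool.resize(k);
  return pool;
}

struct BestSplit {
  int feature = -1;
  double threshold = NA_REAL;
  double gain = 0.0;
  bool found = false;
};

// Best admissible Gini split for one node over the candidate features.
// Columns are presorted once per forest; each node-feature pass is a
// linear scan over the sorted order restricted to the node's rows (with
// bootstrap multiplicity in `cnt`).
BestSplit find_split(const NumericMatrix& x,
                     const IntegerVector& y,
                     const std::vector<std::vector<int>>& col_order,
                     const std::vector<int>& cnt,
                     int n_node, int n_pos,
                     const std::vector<int>& candidates,
                     int min_leaf) {
  BestSplit best;
  const double g_parent = gini(n_pos, n_node);
  if (n_pos == 0 || n_pos == n_node) return best;  // pure node

  for (int f : candidates) {
    int left_n = 0, left_pos = 0;
    double last_val = 0.0;
    bool seen = false;
    for (int idx : col_order[f]) {
      const int c = cnt[idx];
      if (c == 0) continue;
      const double v = x(idx, f);
      if (seen && v > last_val &&
          left_n >= min_leaf && n_node - left_n >= min_leaf) {
        double g_children =
          (left_n * gini(left_pos, left_n) +
           (n_node - left_n) * gini(n_pos - left_pos, n_node - left_n)) /
          n_node;
        double gain = g_parent - g_children;
        if (gain > best.gain + 1e-12) {
          best.gain = gain;
          best.feature = f;
          best.threshold = 0.5 * (last_val + v);
          best.found = true;
        }
      }
      left_n += c;
      left_pos += c * y[idx];
      last_val = v;
      seen = true;
      if (n_node - left_n < min_leaf) break;
    }
  }
  return best;
}

struct WorkItem {
  int node_id;
  std::vector<int> rows;
  int depth;
};

}  // namespace

// Grow one forest.  Returns, per tree, the node table columns plus the
// tree's raw impurity-decrease importance vector (sum over its splits of
// in-bag node size times Gini gain).
// [[Rcpp::export(name = ".grow_forest_cpp")]]
List grow_forest_cpp(NumericMatrix x, IntegerVector y, int num_trees,
                     int mtry, int max_depth, int min_leaf, bool bootstrap) {
  const int n = x.nrow();
  const int p = x.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  List trees(num_trees);

  // presort every column once; nodes scan these orders
  std::vector<std::vector<int>> col_order(p, std::vector<int>(n));
  for (int f = 0; f < p; ++f) {
    std::vector<int>& ord = col_order[f];
    for (int i = 0; i < n; ++i) ord[i] = i;
    const double* col = &x(0, f);
    std::sort(ord.begin(), ord.end(),
              [col](int a, int b) { return col[a] < col[b]; });
  }
  std::vector<int> cnt(n, 0);

  for (int t = 0; t < num_trees; ++t) {
    std::vector<int> inbag(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) {
        int j = static_cast<int>(unif_rand() * n);
        if (j >= n) j = n - 1;
        inbag[i] = j;
      }
    } else {
      for (int i = 0; i < n; ++i) inbag[i] = i;
    }

    std::vector<Node> nodes;
    std::vector<double> importance(p, 0.0);
    std::vector<WorkItem> stack;
    nodes.push_back(Node());
    stack.push_back({0, inbag, 0});

    while (!stack.empty()) {
      WorkItem item = std::move(stack.back());
      stack.pop_back();
      Node& self = nodes[item.node_id];
      self.n_node = item.rows.size();
      self.n_pos = 0;
      for (int r : item.rows) self.n_pos += y[r];
      // majority vote; exact tie goes to the negative (non-autistic) class
      self.pred = (2 * self.n_pos > self.n_node) ? 1 : 0;

      if (item.depth >= max_depth || self.n_node < 2 * min_leaf) continue;
      std::vector<int> cand = sample_features(p, mtry);
      for (int r : item.rows) ++cnt[r];
      BestSplit split = find_split(x, y, col_order, cnt,
                                   self.n_node, self.n_pos, cand, min_leaf);
      for (int r : item.rows) cnt[r] = 0;
      if (!split.found) continue;

      std::vector<int> left_rows, right_rows;
      left_rows.reserve(item.rows.size());
      right_rows.reserve(item.rows.size());
      for (int r : item.rows) {
        if (x(r, split.feature) <= split.threshold) left_rows.push_back(r);
        else right_rows.push_back(r);
      }
      importance[split.feature] +=
        static_cast<double>(item.rows.size()) * split.gain;

      int left_id = nodes.size();
      nodes.push_back(Node());
      int right_id = nodes.size();
      nodes.push_back(Node());
      Node& parent = nodes[item.node_id];  // re-borrow after push_back
      parent.left = left_id;
      parent.right = right_id;
      parent.splitvar = split.feature;
      parent.splitval = split.threshold;
      stack.push_back({right_id, std::move(right_rows), item.depth + 1});
      stack.push_back({left_id, std::move(left_rows), item.depth + 1});
    }

    const int k = nodes.size();
    IntegerVector left(k), right(k), splitvar(k), pred(k), n_node(k);
    NumericVector splitval(k);
    LogicalVector terminal(k);
    for (int i = 0; i < k; ++i) {
      left[i] = nodes[i].left;
      right[i] = nodes[i].right;
      splitvar[i] = nodes[i].splitvar;
      splitval[i] = nodes[i].splitval;
      pred[i] = nodes[i].pred;
      n_node[i] = nodes[i].n_node;
      terminal[i] = nodes[i].splitvar < 0;
    }
    trees[t] = List::create(
      Named("left") = left, Named("right") = right,
      Named("splitvar") = splitvar, Named("splitval") = splitval,
      Named("terminal") = terminal, Named("prediction") = pred,
      Named("n_node") = n_node,
      Named("importance") = NumericVector(importance.begin(),
                                          importance.end()));
  }
  return trees;
}

// Positive-class vote share per row of newx, over the forest's trees.
// [[Rcpp::export(name = ".predict_forest_cpp")]]
NumericVector predict_forest_cpp(List trees, NumericMatrix newx) {
  const int n = newx.nrow();
  const int num_trees = trees.size();
  NumericVector votes(n, 0.0);
  for (int t = 0; t < num_trees; ++t) {
    List tree = trees[t];
    IntegerVector left = tree["left"];
    IntegerVector right = tree["right"];
    IntegerVector splitvar = tree["splitvar"];
    NumericVector splitval = tree["splitval"];
    IntegerVector pred = tree["prediction"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (splitvar[node] >= 0) {
        node = (newx(i, splitvar[node]) <= splitval[node])
                 ? left[node] : right[node];
      }
      votes[i] += pred[node];
    }
  }
  for (int i = 0; i < n; ++i) votes[i] /= num_trees;
  return votes;
}
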