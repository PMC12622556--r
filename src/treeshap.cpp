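// Exact path-dependent TreeSHAP for forests of axis-aligned decision trees.
//
// Trees are passed as flat arrays (concatenated over trees, offsets in
// tree_offset). Node encoding: children/feature are -1 at leaves; numeric
// splits send x[feature] <= threshold to the left child. `values` holds one
// output per class per node (only read at leaves); `cover` is the number of
// training rows routed through each node and defines the conditional
// expectations of the path-dependent convention.

#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

namespace {

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

void extend_path(PathElement *unique_path, int unique_depth,
                 double zero_fraction, double one_fraction,
                 int feature_index) {
  unique_path[unique_depth].feature_index = feature_index;
  unique_path[unique_depth].zero_fraction = zero_fraction;
  unique_path[unique_depth].one_fraction = one_fraction;
  unique_path[unique_depth].pweight = (unique_depth == 0 ? 1.0 : 0.0);
  for (int i = unique_depth - 1; i >= 0; --i) {
    unique_path[i + 1].pweight += one_fraction * unique_path[i].pweight *
                                  (i + 1) / static_cast<double>(unique_depth + 1);
    unique_path[i].pweight = zero_fraction * unique_path[i].pweight *
                             (unique_depth - i) /
                             static_cast<double>(unique_depth + 1);
  }
}

void unwind_path(PathElement *unique_path, int unique_depth, int path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = unique_path[i].pweight;
      unique_path[i].pweight = next_one_portion * (unique_depth + 1) /
                               static_cast<double>((i + 1) * one_fraction);
      next_one_portion = tmp - unique_path[i].pweight * zero_fraction *
                               (unique_depth - i) /
                               static_cast<double>(unique_depth + 1);
    } else {
      unique_path[i].pweight = (unique_path[i].pweight * (unique_depth + 1)) /
                               (zero_fraction * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    unique_path[i].feature_index = unique_path[i + 1].feature_index;
    unique_path[i].zero_fraction = unique_path[i + 1].zero_fraction;
    unique_path[i].one_fraction = unique_path[i + 1].one_fraction;
  }
}

double unwound_path_sum(const PathElement *unique_path, int unique_depth,
                        int path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;
  double total = 0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = next_one_portion * (unique_depth + 1) /
                         static_cast<double>((i + 1) * one_fraction);
      total += tmp;
      next_one_portion = unique_path[i].pweight - tmp * zero_fraction *
                             (unique_depth - i) /
                             static_cast<double>(unique_depth + 1);
    } else {
      total += (unique_path[i].pweight / zero_fraction) /
               ((unique_depth - i) / static_cast<double>(unique_depth + 1));
    }
  }
  return total;
}

struct TreeView {
  const int *left;
  const int *right;
  const int *feature;
  const double *threshold;
  const double *cover;
  const double *values;   // n_nodes x n_class, column-major slice
  int n_nodes;
  int n_class;
};

// phi: p x n_class accumulator for one sample (column-major)
void tree_shap_recursive(const TreeView &tree, const double *x, double *phi,
                         int p, int node, int unique_depth,
                         PathElement *parent_unique_path,
                         double parent_zero_fraction,
                         double parent_one_fraction,
                         int parent_feature_index) {
  PathElement *unique_path = parent_unique_path + unique_depth + 1;
  std::memcpy(unique_path, parent_unique_path,
              (unique_depth + 1) * sizeof(PathElement));
  extend_path(unique_path, unique_depth, parent_zero_fraction,
              parent_one_fraction, parent_feature_index);

  if (tree.feature[node] < 0) {  // leaf
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(unique_path, unique_depth, i);
      const PathElement &el = unique_path[i];
      const double scale = w * (el.one_fraction - el.zero_fraction);
      for (int c = 0; c < tree.n_class; ++c) {
        phi[el.feature_index + c * p] +=
            scale * tree.values[node + c * tree.n_nodes];
      }
    }
    return;
  }

  const int split = tree.feature[node];
  const int hot = (x[split] <= tree.threshold[node]) ? tree.left[node]
                                                     : tree.right[node];
  const int cold = (hot == tree.left[node]) ? tree.right[node]
                                            : tree.left[node];
  const double w_node = tree.cover[node];
  const double hot_zero = tree.cover[hot] / w_node;
  const double cold_zero = tree.cover[cold] / w_node;

  double incoming_zero = 1.0, incoming_one = 1.0;
  int path_index = 0;
  for (; path_index <= unique_depth; ++path_index) {
    if (unique_path[path_index].feature_index == split) break;
  }
  if (path_index != unique_depth + 1) {
    incoming_zero = unique_path[path_index].zero_fraction;
    incoming_one = unique_path[path_index].one_fraction;
    unwind_path(unique_path, unique_depth, path_index);
    unique_depth -= 1;
  }

  tree_shap_recursive(tree, x, phi, p, hot, unique_depth + 1, unique_path,
                      incoming_zero * hot_zero, incoming_one, split);
  tree_shap_recursive(tree, x, phi, p, cold, unique_depth + 1, unique_path,
                      incoming_zero * cold_zero, 0.0, split);
}

int tree_max_depth(const TreeView &tree, int node, int depth) {
  if (tree.feature[node] < 0) return depth;
  int l = tree_max_depth(tree, tree.left[node], depth + 1);
  int r = tree_max_depth(tree, tree.right[node], depth + 1);
  return l > r ? l : r;
}

}  // namespace

// Count training rows routed through every node of every tree.
// [[Rcpp::export]]
NumericVector rcpp_node_cover(IntegerVector tree_offset, IntegerVector left,
                              IntegerVector right, IntegerVector feature,
                              NumericVector threshold, NumericMatrix X) {
  const int n_trees = tree_offset.size() - 1;
  const int n = X.nrow();
  NumericVector cover(left.size());
  for (int t = 0; t < n_trees; ++t) {
    const int off = tree_offset[t];
    for (int r = 0; r < n; ++r) {
      int node = off;
      for (;;) {
        cover[node] += 1;
        const int f = feature[node];
        if (f < 0) break;
        node = off + ((X(r, f) <= threshold[node]) ? left[node] : right[node]);
      }
    }
  }
  return cover;
}

// Forest SHAP values, averaged over trees (matching a forest output that is
// the mean of per-tree leaf values). Returns phi (n x p x n_class) and the
// per-class base value (cover-weighted mean of leaf values).
// [[Rcpp::export]]
List rcpp_forest_shap(IntegerVector tree_offset, IntegerVector left,
                      IntegerVector right, IntegerVector feature,
                      NumericVector threshold, NumericMatrix values,
                      NumericVector cover, NumericMatrix X, int n_class) {
  const int n_trees = tree_offset.size() - 1;
  const int n = X.nrow();
  const int p = X.ncol();
  const int total_nodes = left.size();

  NumericVector phi(static_cast<R_xlen_t>(n) * p * n_class);
  NumericVector base(n_class);

  std::vector<TreeView> trees(n_trees);
  std::vector<std::vector<double>> tree_values(n_trees);
  int global_max_depth = 0;
  for (int t = 0; t < n_trees; ++t) {
    const int off = tree_offset[t];
    const int nn = tree_offset[t + 1] - off;
    TreeView &tv = trees[t];
    // re-slice values into a per-tree column-major block
    tree_values[t].resize(static_cast<size_t>(nn) * n_class);
    for (int c = 0; c < n_class; ++c)
      for (int j = 0; j < nn; ++j)
        tree_values[t][j + static_cast<size_t>(c) * nn] =
            values(off + j, c);
    tv.left = &left[off];
    tv.right = &right[off];
    tv.feature = &feature[off];
    tv.threshold = &threshold[off];
    tv.cover = &cover[off];
    tv.values = tree_values[t].data();
    tv.n_nodes = nn;
    tv.n_class = n_class;
    const int d = tree_max_depth(tv, 0, 0);
    if (d > global_max_depth) global_max_depth = d;
    // base value: cover-weighted leaf mean
    const double root_cover = tv.cover[0];
    for (int j = 0; j < nn; ++j) {
      if (tv.feature[j] < 0) {
        const double w = tv.cover[j] / root_cover;
        for (int c = 0; c < n_class; ++c)
          base[c] += w * tv.values[j + static_cast<size_t>(c) * nn] / n_trees;
      }
    }
  }

  const int maxd = global_max_depth + 2;
  std::vector<PathElement> path_buf(static_cast<size_t>(maxd) * (maxd + 1) / 2 +
                                    maxd + 2);
  std::vector<double> x(p), phi_row(static_cast<size_t>(p) * n_class);

  for (int r = 0; r < n; ++r) {
    for (int j = 0; j < p; ++j) x[j] = X(r, j);
    std::fill(phi_row.begin(), phi_row.end(), 0.0);
    for (int t = 0; t < n_trees; ++t) {
      tree_shap_recursive(trees[t], x.data(), phi_row.data(), p, 0, 0,
                          path_buf.data(), 1.0, 1.0, -1);
    }
    for (int c = 0; c < n_class; ++c)
      for (int j = 0; j < p; ++j)
        phi[r + static_cast<R_xlen_t>(j) * n +
            static_cast<R_xlen_t>(c) * n * p] =
            phi_row[j + static_cast<size_t>(c) * p] / n_trees;
  }

  phi.attr("dim") = IntegerVector::create(n, p, n_class);
  return List::create(_["phi"] = phi, _["base"] = base);
}

// Conditional expectation E[f(x) | x_S] under the path-dependent convention;
// used by tests as an independent oracle building block and by predictions
// from extracted structures.
// [[Rcpp::export]]
NumericMatrix rcpp_tree_predict(IntegerVector tree_offset, IntegerVector left,
                                IntegerVector right, IntegerVector feature,
                                NumericVector threshold, NumericMatrix values,
                                NumericMatrix X, int n_class) {
  const int n_trees = tree_offset.size() - 1;
  const int n = X.nrow();
  NumericMatrix out(n, n_class);
  for (int t = 0; t < n_trees; ++t) {
    const int off = tree_offset[t];
    for (int r = 0; r < n; ++r) {
      int node = off;
      while (feature[node] >= 0) {
        node = off +
               ((X(r, feature[node]) <= threshold[node]) ? left[node]
                                                         : right[node]);
      }
      for (int c = 0; c < n_class; ++c)
        out(r, c) += values(node, c) / n_trees;
    }
  }
  return out;
}
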