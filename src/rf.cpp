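// Classification random forest: bootstrap + CART with Gini splits,
// out-of-bag error, permutation importance (mean decrease accuracy) and
// Gini importance. Self-contained so that results are bit-reproducible
// from a single integer seed (std::mt19937_64; no std::*_distribution,
// whose output is implementation-defined).
#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold; // x[feature] <= threshold goes left
  int left, right;  // child node indices
  int pred;         // leaf class (0/1), -1 for internal
};

struct Tree {
  std::vector<Node> nodes;
  std::vector<int> used; // features appearing in at least one split
};

inline std::uint64_t draw(std::mt19937_64 &rng, std::uint64_t n) {
  return rng() % n; // modulo bias negligible for n << 2^64
}

inline double gini(int n0, int n1) {
  double n = n0 + n1;
  if (n <= 0) return 0.0;
  double p0 = n0 / n, p1 = n1 / n;
  return 1.0 - p0 * p0 - p1 * p1;
}

// Grow one tree on rows `idx` of X (column-major n x p), labels y (0/1).
// Accumulates Gini importance into imp_gini.
Tree grow_tree(const NumericMatrix &X, const IntegerVector &y,
               std::vector<int> idx, int mtry, int min_node,
               std::mt19937_64 &rng, std::vector<double> &imp_gini) {
  const int p = X.ncol();
  Tree tree;
  std::vector<bool> used_flag(p, false);

  // stack of (node_id, sample indices)
  struct Work { int node; std::vector<int> idx; };
  std::vector<Work> stack;
  tree.nodes.push_back(Node{-1, 0.0, -1, -1, -1});
  stack.push_back(Work{0, std::move(idx)});

  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;

  while (!stack.empty()) {
    Work w = std::move(stack.back());
    stack.pop_back();
    std::vector<int> &rows = w.idx;
    const int n = (int)rows.size();
    int n1 = 0;
    for (int i : rows) n1 += y[i];
    int n0 = n - n1;

    auto make_leaf = [&](void) {
      int cls;
      if (n1 > n0) cls = 1;
      else if (n0 > n1) cls = 0;
      else cls = (int)(rng() & 1u);
      tree.nodes[w.node].pred = cls;
    };

    if (n0 == 0 || n1 == 0 || n <= min_node) { make_leaf(); continue; }

    // sample mtry features without replacement (partial Fisher-Yates)
    int best_f = -1, best_nl = 0;
    double best_thr = 0.0, best_dec = 0.0;
    double g_parent = gini(n0, n1);
    std::vector<std::pair<double,int>> vals(n);
    for (int t = 0; t < mtry; ++t) {
      int r = t + (int)draw(rng, (std::uint64_t)(p - t));
      std::swap(feats[t], feats[r]);
      int f = feats[t];
      for (int i = 0; i < n; ++i)
        vals[i] = std::make_pair(X(rows[i], f), rows[i]);
      std::sort(vals.begin(), vals.end());
      int nl0 = 0, nl1 = 0;
      for (int i = 0; i + 1 < n; ++i) {
        if (y[vals[i].second] == 1) ++nl1; else ++nl0;
        if (vals[i].first == vals[i + 1].first) continue;
        int nl = nl0 + nl1, nr = n - nl;
        double dec = g_parent -
          (nl / (double)n) * gini(nl0, nl1) -
          (nr / (double)n) * gini(n0 - nl0, n1 - nl1);
        if (dec > best_dec + 1e-15) {
          best_dec = dec;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
          best_nl = nl;
        }
      }
    }

    if (best_f < 0) { make_leaf(); continue; }

    imp_gini[best_f] += best_dec * n;
    if (!used_flag[best_f]) { used_flag[best_f] = true; tree.used.push_back(best_f); }

    std::vector<int> left_rows, right_rows;
    left_rows.reserve(best_nl);
    right_rows.reserve(n - best_nl);
    for (int i : rows) {
      if (X(i, best_f) <= best_thr) left_rows.push_back(i);
      else right_rows.push_back(i);
    }
    int li = (int)tree.nodes.size();
    tree.nodes.push_back(Node{-1, 0.0, -1, -1, -1});
    int ri = (int)tree.nodes.size();
    tree.nodes.push_back(Node{-1, 0.0, -1, -1, -1});
    tree.nodes[w.node] = Node{best_f, best_thr, li, ri, -1};
    stack.push_back(Work{li, std::move(left_rows)});
    stack.push_back(Work{ri, std::move(right_rows)});
  }
  return tree;
}

inline int predict_row(const Tree &tree, const NumericMatrix &X, int i,
                       const std::vector<double> *override_col = nullptr,
                       int override_f = -1) {
  int node = 0;
  while (tree.nodes[node].pred < 0) {
    const Node &nd = tree.nodes[node];
    double v = (override_col && nd.feature == override_f)
      ? (*override_col)[i] : X(i, nd.feature);
    node = (v <= nd.threshold) ? nd.left : nd.right;
  }
  return tree.nodes[node].pred;
}

NumericMatrix serialize_tree(const Tree &tree) {
  int m = (int)tree.nodes.size();
  NumericMatrix out(m, 5);
  for (int i = 0; i < m; ++i) {
    const Node &nd = tree.nodes[i];
    out(i, 0) = nd.feature;
    out(i, 1) = nd.threshold;
    out(i, 2) = nd.left;
    out(i, 3) = nd.right;
    out(i, 4) = nd.pred;
  }
  return out;
}

Tree deserialize_tree(const NumericMatrix &m) {
  Tree tree;
  tree.nodes.resize(m.nrow());
  for (int i = 0; i < m.nrow(); ++i)
    tree.nodes[i] = Node{(int)m(i, 0), m(i, 1), (int)m(i, 2), (int)m(i, 3),
                         (int)m(i, 4)};
  return tree;
}

} // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                int min_node, double seed, bool importance) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) must equal nrow(X)");
  if (mtry < 1 || mtry > p) stop("mtry out of range");
  std::mt19937_64 rng((std::uint64_t)seed);

  std::vector<double> imp_gini(p, 0.0), imp_mda(p, 0.0);
  std::vector<double> oob_votes1(n, 0.0), oob_n(n, 0.0);
  List trees(n_trees);
  std::vector<int> perm_idx;
  std::vector<double> perm_col(n);

  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> boot(n);
    std::vector<bool> inbag(n, false);
    for (int i = 0; i < n; ++i) {
      int r = (int)draw(rng, (std::uint64_t)n);
      boot[i] = r;
      inbag[r] = true;
    }
    Tree tree = grow_tree(X, y, boot, mtry, min_node, rng, imp_gini);
    trees[t] = serialize_tree(tree);

    std::vector<int> oob;
    for (int i = 0; i < n; ++i) if (!inbag[i]) oob.push_back(i);
    if (!oob.empty()) {
      int correct = 0;
      for (int i : oob) {
        int pr = predict_row(tree, X, i);
        oob_votes1[i] += pr;
        oob_n[i] += 1.0;
        if (pr == y[i]) ++correct;
      }
      if (importance) {
        // permute each used feature's values over the OOB rows
        for (int f : tree.used) {
          perm_idx = oob;
          for (int i = (int)perm_idx.size() - 1; i > 0; --i) {
            int r = (int)draw(rng, (std::uint64_t)(i + 1));
            std::swap(perm_idx[i], perm_idx[r]);
          }
          for (size_t k = 0; k < oob.size(); ++k)
            perm_col[oob[k]] = X(perm_idx[k], f);
          int correct_perm = 0;
          for (int i : oob) {
            if (predict_row(tree, X, i, &perm_col, f) == y[i]) ++correct_perm;
          }
          imp_mda[f] += (correct - correct_perm) / (double)oob.size();
        }
      }
    }
  }

  NumericVector oob_frac(n), mda(p), gini_imp(p);
  int n_scored = 0, n_wrong = 0;
  for (int i = 0; i < n; ++i) {
    if (oob_n[i] > 0) {
      oob_frac[i] = oob_votes1[i] / oob_n[i];
      ++n_scored;
      if ((oob_frac[i] > 0.5 ? 1 : 0) != y[i]) ++n_wrong;
    } else {
      oob_frac[i] = NA_REAL;
    }
  }
  double oob_err = n_scored > 0 ? n_wrong / (double)n_scored : NA_REAL;
  for (int j = 0; j < p; ++j) {
    mda[j] = imp_mda[j] / n_trees;
    gini_imp[j] = imp_gini[j] / n_trees;
  }

  return List::create(_["trees"] = trees, _["oob_votes"] = oob_frac,
                      _["oob_error"] = oob_err, _["mda"] = mda,
                      _["gini"] = gini_imp, _["n_trees"] = n_trees,
                      _["mtry"] = mtry);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector votes(n);
  int nt = trees.size();
  for (int t = 0; t < nt; ++t) {
    Tree tree = deserialize_tree(as<NumericMatrix>(trees[t]));
    for (int i = 0; i < n; ++i) votes[i] += predict_row(tree, X, i);
  }
  for (int i = 0; i < n; ++i) votes[i] /= nt;
  return votes;
}
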