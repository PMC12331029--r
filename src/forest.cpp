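// Random-forest classifier used for position decoding: CART trees with Gini
// impurity, bootstrap resampling, sqrt(p) feature subsampling, nodes expanded
// until pure or with fewer than two samples to split, one sample minimum per
// leaf, equal sample weights. A self-contained LCG supplies the randomness so
// fits are bit-reproducible across compilers (std:: distributions are
// implementation-defined).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed * 2862933555777941757ULL + 3037000493ULL) {}
  uint64_t next() {
    s = s * 6364136223846793005ULL + 1442695040888963407ULL;
    return s >> 17;
  }
  int randint(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Tree {
  std::vector<int> feature, left, right, pred;
  std::vector<double> threshold;
  int add_node() {
    feature.push_back(-1); left.push_back(-1); right.push_back(-1);
    pred.push_back(-1); threshold.push_back(0.0);
    return static_cast<int>(feature.size()) - 1;
  }
};

struct Builder {
  const Rcpp::NumericMatrix& X;
  const std::vector<int>& y;
  int n_classes, mtry;
  Rng& rng;
  Tree& tree;
  std::vector<int> feat_pool;

  Builder(const Rcpp::NumericMatrix& X_, const std::vector<int>& y_,
          int n_classes_, int mtry_, Rng& rng_, Tree& tree_)
      : X(X_), y(y_), n_classes(n_classes_), mtry(mtry_), rng(rng_),
        tree(tree_), feat_pool(X_.ncol()) {
    for (int j = 0; j < X.ncol(); ++j) feat_pool[j] = j;
  }

  int majority(const std::vector<int>& idx) {
    std::vector<int> cnt(n_classes, 0);
    for (int i : idx) cnt[y[i]]++;
    return static_cast<int>(std::max_element(cnt.begin(), cnt.end()) - cnt.begin());
  }

  bool pure(const std::vector<int>& idx) {
    for (size_t k = 1; k < idx.size(); ++k)
      if (y[idx[k]] != y[idx[0]]) return false;
    return true;
  }

  int build(std::vector<int>& idx) {
    int node = tree.add_node();
    if (idx.size() < 2 || pure(idx)) {
      tree.pred[node] = majority(idx);
      return node;
    }
    // draw mtry candidate features (partial Fisher-Yates)
    int p = static_cast<int>(feat_pool.size());
    for (int k = 0; k < mtry; ++k) {
      int j = k + rng.randint(p - k);
      std::swap(feat_pool[k], feat_pool[j]);
    }
    double best_score = -1.0;
    int best_f = -1;
    double best_thr = 0.0;
    int n = static_cast<int>(idx.size());
    std::vector<int> order(idx);
    std::vector<int> cntL(n_classes), cntR(n_classes);
    for (int k = 0; k < mtry; ++k) {
      int f = feat_pool[k];
      std::sort(order.begin(), order.end(), [&](int a, int b) {
        double va = X(a, f), vb = X(b, f);
        if (va != vb) return va < vb;
        return a < b;  // stable, deterministic
      });
      if (X(order[0], f) == X(order[n - 1], f)) continue;  // constant feature
      std::fill(cntL.begin(), cntL.end(), 0);
      std::fill(cntR.begin(), cntR.end(), 0);
      for (int i : order) cntR[y[i]]++;
      double s2L = 0.0, s2R = 0.0;
      for (int c = 0; c < n_classes; ++c) s2R += double(cntR[c]) * cntR[c];
      for (int i = 0; i < n - 1; ++i) {
        int c = y[order[i]];
        s2L += 2.0 * cntL[c] + 1.0;
        s2R -= 2.0 * cntR[c] - 1.0;
        cntL[c]++; cntR[c]--;
        double v = X(order[i], f), vn = X(order[i + 1], f);
        if (v == vn) continue;
        // maximizing s2L/nL + s2R/nR minimizes the weighted child Gini
        double score = s2L / (i + 1) + s2R / (n - i - 1);
        if (score > best_score) {
          best_score = score;
          best_f = f;
          best_thr = v + (vn - v) / 2.0;
        }
      }
    }
    if (best_f < 0) {  // all sampled features constant on this node
      tree.pred[node] = majority(idx);
      return node;
    }
    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, best_f) <= best_thr) li.push_back(i); else ri.push_back(i);
    }
    tree.feature[node] = best_f;
    tree.threshold[node] = best_thr;
    tree.left[node] = build(li);
    tree.right[node] = build(ri);
    return node;
  }
};

int predict_one(const Tree& t, const Rcpp::NumericMatrix& X, int row) {
  int node = 0;
  while (t.pred[node] < 0) {
    node = (X(row, t.feature[node]) <= t.threshold[node]) ? t.left[node]
                                                          : t.right[node];
  }
  return t.pred[node];
}

}  // namespace

// [[Rcpp::export(rng = false)]]
Rcpp::IntegerMatrix rf_votes(Rcpp::NumericMatrix X_train,
                             Rcpp::IntegerVector y_train,
                             Rcpp::NumericMatrix X_test,
                             int n_classes, int n_trees, int mtry,
                             double seed) {
  int n = X_train.nrow();
  if (n < 1) Rcpp::stop("empty training set");
  if (mtry < 1) mtry = 1;
  if (mtry > X_train.ncol()) mtry = X_train.ncol();
  std::vector<int> y(y_train.begin(), y_train.end());
  Rcpp::IntegerMatrix votes(X_test.nrow(), n_classes);
  Rng rng(static_cast<uint64_t>(seed) + 0x9e3779b97f4a7c15ULL);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> boot(n);
    for (int i = 0; i < n; ++i) boot[i] = rng.randint(n);
    Tree tree;
    Builder b(X_train, y, n_classes, mtry, rng, tree);
    b.build(boot);
    for (int r = 0; r < X_test.nrow(); ++r)
      votes(r, predict_one(tree, X_test, r))++;
  }
  return votes;
}
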