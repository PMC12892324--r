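// Compact base learners for the undersampling vote ensembles.
//
// Three binary classifiers with the conventional parameterizations:
//   - random forest of gini CART trees (bootstrap + sqrt(p) feature sampling)
//   - gradient-boosted regression trees on logistic loss (exact greedy split)
//   - C-SVC trained by simplified SMO (linear / RBF kernel)
//
// Trees are stored as flat matrices, one row per node:
//   col 0 feature (0-based, -1 for leaf), col 1 threshold,
//   col 2 left child, col 3 right child, col 4 value
// For forest trees `value` is the leaf's fraction of positives; for boosted
// trees it is the additive leaf weight (learning rate already applied).
//
// All randomness flows through a std::mt19937 seeded from R so results are
// reproducible across platforms for a fixed seed.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct FlatTree {
  std::vector<double> feature, threshold, left, right, value;
  int add_node() {
    feature.push_back(-1); threshold.push_back(0);
    left.push_back(-1); right.push_back(-1); value.push_back(0);
    return (int)feature.size() - 1;
  }
  NumericMatrix as_matrix() const {
    int n = (int)feature.size();
    NumericMatrix m(n, 5);
    for (int i = 0; i < n; ++i) {
      m(i, 0) = feature[i]; m(i, 1) = threshold[i];
      m(i, 2) = left[i];    m(i, 3) = right[i];   m(i, 4) = value[i];
    }
    return m;
  }
};

double tree_predict_row(const NumericMatrix& tree, const NumericMatrix& X,
                        int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    int f = (int)tree(node, 0);
    node = (X(row, f) <= tree(node, 1)) ? (int)tree(node, 2)
                                        : (int)tree(node, 3);
  }
  return tree(node, 4);
}

// ---------------------------------------------------------------- CART / RF

struct CartBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;  // 0/1
  int max_depth;           // <= 0 means unlimited
  int mtry;
  std::mt19937& rng;
  FlatTree tree;
  std::vector<int> feat_pool;

  CartBuilder(const NumericMatrix& X_, const IntegerVector& y_, int max_depth_,
              int mtry_, std::mt19937& rng_)
      : X(X_), y(y_), max_depth(max_depth_), mtry(mtry_), rng(rng_) {
    feat_pool.resize(X.ncol());
    for (int j = 0; j < X.ncol(); ++j) feat_pool[j] = j;
  }

  int build(std::vector<int>& idx, int depth) {
    int node = tree.add_node();
    int n = (int)idx.size();
    int pos = 0;
    for (int i : idx) pos += y[i];
    double p = (double)pos / n;
    tree.value[node] = p;
    bool stop = (pos == 0 || pos == n || n < 2 ||
                 (max_depth > 0 && depth >= max_depth));
    if (stop) return node;

    // sample mtry candidate features without replacement
    int p_all = (int)feat_pool.size();
    int m = std::min(mtry, p_all);
    for (int j = 0; j < m; ++j) {
      std::uniform_int_distribution<int> d(j, p_all - 1);
      std::swap(feat_pool[j], feat_pool[d(rng)]);
    }

    double best_score = std::numeric_limits<double>::infinity();
    int best_f = -1;
    double best_thr = 0;
    std::vector<int> order(idx);
    for (int jj = 0; jj < m; ++jj) {
      int f = feat_pool[jj];
      std::sort(order.begin(), order.end(), [&](int a, int b) {
        return X(a, f) < X(b, f);
      });
      int pos_l = 0;
      for (int k = 0; k < n - 1; ++k) {
        pos_l += y[order[k]];
        double xv = X(order[k], f), xn = X(order[k + 1], f);
        if (xv == xn) continue;
        int nl = k + 1, nr = n - nl;
        int pos_r = pos - pos_l;
        double pl = (double)pos_l / nl, pr = (double)pos_r / nr;
        double gini = nl * 2.0 * pl * (1 - pl) + nr * 2.0 * pr * (1 - pr);
        if (gini < best_score) {
          best_score = gini;
          best_f = f;
          best_thr = xv + (xn - xv) / 2.0;
        }
      }
    }
    if (best_f < 0) return node;  // all candidates constant

    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, best_f) <= best_thr) li.push_back(i); else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) return node;
    tree.feature[node] = best_f;
    tree.threshold[node] = best_thr;
    int l = build(li, depth + 1);
    int r = build(ri, depth + 1);
    tree.left[node] = l;
    tree.right[node] = r;
    return node;
  }
};

// ------------------------------------------------- boosted regression trees

struct BoostBuilder {
  const NumericMatrix& X;
  const std::vector<double>& grad;
  const std::vector<double>& hess;
  int max_depth;
  double lambda, eta, min_child_weight;
  FlatTree tree;

  BoostBuilder(const NumericMatrix& X_, const std::vector<double>& g,
               const std::vector<double>& h, int max_depth_, double lambda_,
               double eta_, double mcw)
      : X(X_), grad(g), hess(h), max_depth(max_depth_), lambda(lambda_),
        eta(eta_), min_child_weight(mcw) {}

  int build(std::vector<int>& idx, int depth) {
    int node = tree.add_node();
    double G = 0, H = 0;
    for (int i : idx) { G += grad[i]; H += hess[i]; }
    tree.value[node] = -eta * G / (H + lambda);
    if (depth >= max_depth || idx.size() < 2) return node;

    double parent_obj = G * G / (H + lambda);
    double best_gain = 1e-12;  // require strictly positive gain
    int best_f = -1;
    double best_thr = 0;
    int n = (int)idx.size();
    std::vector<int> order(idx);
    for (int f = 0; f < X.ncol(); ++f) {
      std::sort(order.begin(), order.end(), [&](int a, int b) {
        return X(a, f) < X(b, f);
      });
      double GL = 0, HL = 0;
      for (int k = 0; k < n - 1; ++k) {
        GL += grad[order[k]]; HL += hess[order[k]];
        double xv = X(order[k], f), xn = X(order[k + 1], f);
        if (xv == xn) continue;
        double GR = G - GL, HR = H - HL;
        if (HL < min_child_weight || HR < min_child_weight) continue;
        double gain = 0.5 * (GL * GL / (HL + lambda) + GR * GR / (HR + lambda)
                             - parent_obj);
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = xv + (xn - xv) / 2.0;
        }
      }
    }
    if (best_f < 0) return node;
    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, best_f) <= best_thr) li.push_back(i); else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) return node;
    tree.feature[node] = best_f;
    tree.threshold[node] = best_thr;
    tree.left[node] = build(li, depth + 1);
    tree.right[node] = build(ri, depth + 1);
    return node;
  }
};

double kernel_eval(const NumericMatrix& A, int i, const NumericMatrix& B,
                   int j, int kernel, double gamma) {
  int p = A.ncol();
  if (kernel == 0) {  // linear
    double s = 0;
    for (int k = 0; k < p; ++k) s += A(i, k) * B(j, k);
    return s;
  }
  double d = 0;  // rbf
  for (int k = 0; k < p; ++k) {
    double t = A(i, k) - B(j, k);
    d += t * t;
  }
  return std::exp(-gamma * d);
}

}  // namespace

// [[Rcpp::export(name = ".fit_forest_cpp")]]
List fit_forest_cpp(NumericMatrix X, IntegerVector y, int n_trees,
                    int max_depth, int mtry, int seed) {
  std::mt19937 rng((unsigned)seed);
  int n = X.nrow();
  List trees(n_trees);
  std::uniform_int_distribution<int> boot(0, n - 1);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    CartBuilder cb(X, y, max_depth, mtry, rng);
    cb.build(idx, 0);
    trees[t] = cb.tree.as_matrix();
  }
  return trees;
}

// [[Rcpp::export(name = ".predict_forest_cpp")]]
NumericVector predict_forest_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) out[i] += tree_predict_row(tree, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}

// [[Rcpp::export(name = ".fit_xgb_cpp")]]
List fit_xgb_cpp(NumericMatrix X, IntegerVector y, int n_rounds, int max_depth,
                 double eta, double lambda, double min_child_weight) {
  int n = X.nrow();
  std::vector<double> margin(n, 0.0), grad(n), hess(n);
  List trees(n_rounds);
  for (int t = 0; t < n_rounds; ++t) {
    for (int i = 0; i < n; ++i) {
      double p = 1.0 / (1.0 + std::exp(-margin[i]));
      grad[i] = p - y[i];
      hess[i] = std::max(p * (1 - p), 1e-16);
    }
    BoostBuilder bb(X, grad, hess, max_depth, lambda, eta, min_child_weight);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    bb.build(idx, 0);
    NumericMatrix tree = bb.tree.as_matrix();
    trees[t] = tree;
    for (int i = 0; i < n; ++i) margin[i] += tree_predict_row(tree, X, i);
  }
  return trees;
}

// [[Rcpp::export(name = ".predict_xgb_cpp")]]
NumericVector predict_xgb_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), T = trees.size();
  NumericVector margin(n);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) margin[i] += tree_predict_row(tree, X, i);
  }
  return margin;  // logit scale; caller applies sigmoid / threshold at 0
}

// Simplified SMO (Platt-style working pair selection with a random partner).
// [[Rcpp::export(name = ".fit_svm_cpp")]]
List fit_svm_cpp(NumericMatrix X, NumericVector y, double C, int kernel,
                 double gamma, double tol, int max_passes, int seed) {
  int n = X.nrow();
  std::mt19937 rng((unsigned)seed);
  std::vector<double> alpha(n, 0.0);
  double b = 0;
  NumericMatrix K(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) K(i, j) = K(j, i) = kernel_eval(X, i, X, j, kernel, gamma);

  auto f = [&](int i) {
    double s = b;
    for (int j = 0; j < n; ++j)
      if (alpha[j] > 0) s += alpha[j] * y[j] * K(i, j);
    return s;
  };

  int passes = 0, iter = 0, max_iter = 200 * std::max(n, 50);
  std::uniform_int_distribution<int> pick(0, n - 2);
  while (passes < max_passes && iter < max_iter) {
    int changed = 0;
    for (int i = 0; i < n; ++i) {
      ++iter;
      double Ei = f(i) - y[i];
      if ((y[i] * Ei < -tol && alpha[i] < C) ||
          (y[i] * Ei > tol && alpha[i] > 0)) {
        int j = pick(rng);
        if (j >= i) ++j;
        double Ej = f(j) - y[j];
        double ai_old = alpha[i], aj_old = alpha[j];
        double L, H;
        if (y[i] != y[j]) {
          L = std::max(0.0, aj_old - ai_old);
          H = std::min(C, C + aj_old - ai_old);
        } else {
          L = std::max(0.0, ai_old + aj_old - C);
          H = std::min(C, ai_old + aj_old);
        }
        if (L >= H) continue;
        double eta_ = 2 * K(i, j) - K(i, i) - K(j, j);
        if (eta_ >= 0) continue;
        double aj = aj_old - y[j] * (Ei - Ej) / eta_;
        aj = std::min(H, std::max(L, aj));
        if (std::fabs(aj - aj_old) < 1e-7) continue;
        double ai = ai_old + y[i] * y[j] * (aj_old - aj);
        alpha[i] = ai;
        alpha[j] = aj;
        double b1 = b - Ei - y[i] * (ai - ai_old) * K(i, i)
                    - y[j] * (aj - aj_old) * K(i, j);
        double b2 = b - Ej - y[i] * (ai - ai_old) * K(i, j)
                    - y[j] * (aj - aj_old) * K(j, j);
        if (ai > 0 && ai < C) b = b1;
        else if (aj > 0 && aj < C) b = b2;
        else b = (b1 + b2) / 2;
        ++changed;
      }
    }
    passes = (changed == 0) ? passes + 1 : 0;
  }

  // keep support vectors only
  std::vector<int> sv;
  for (int i = 0; i < n; ++i) if (alpha[i] > 1e-10) sv.push_back(i);
  int ns = (int)sv.size();
  NumericMatrix svX(ns, X.ncol());
  NumericVector coef(ns);
  for (int s = 0; s < ns; ++s) {
    coef[s] = alpha[sv[s]] * y[sv[s]];
    for (int k = 0; k < X.ncol(); ++k) svX(s, k) = X(sv[s], k);
  }
  return List::create(_["sv"] = svX, _["coef"] = coef, _["b"] = b);
}

// [[Rcpp::export(name = ".predict_svm_cpp")]]
NumericVector predict_svm_cpp(NumericMatrix svX, NumericVector coef, double b,
                              int kernel, double gamma, NumericMatrix X) {
  int n = X.nrow(), ns = svX.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = b;
    for (int j = 0; j < ns; ++j) s += coef[j] * kernel_eval(X, i, svX, j, kernel, gamma);
    out[i] = s;
  }
  return out;
}
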