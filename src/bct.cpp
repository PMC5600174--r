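// Stage-wise gradient boosting on Bernoulli deviance with shallow,
// best-first least-squares regression trees and Newton leaf values.
// The hot loops live here; all user-facing contracts are on the R side.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

constexpr double kEps = 1e-12;

inline double logistic(double f) { return 1.0 / (1.0 + std::exp(-f)); }

inline double bern_dev(const std::vector<double>& p, const NumericVector& y) {
  double d = 0.0;
  const int n = y.size();
  for (int i = 0; i < n; ++i) {
    double pi = std::min(1.0 - kEps, std::max(kEps, p[i]));
    d += y[i] * std::log(pi) + (1.0 - y[i]) * std::log(1.0 - pi);
  }
  return -2.0 * d / n;
}

struct SplitInfo {
  int var = -1;
  double split = 0.0;
  double improve = 0.0;
};

// Best least-squares split of rows with member[i] == node_id.
// Split criterion: reduction in SSE of the working response z,
//   imp = sum_l^2/n_l + sum_r^2/n_r - sum^2/n  (>= 0).
SplitInfo best_split(const NumericMatrix& X,
                     const std::vector<std::vector<int> >& order,
                     const std::vector<double>& z,
                     const std::vector<int>& member,
                     int node_id, int min_obs) {
  SplitInfo best;
  const int p = X.ncol();
  double sum_t = 0.0;
  int n_t = 0;
  const int n = X.nrow();
  for (int i = 0; i < n; ++i)
    if (member[i] == node_id) { sum_t += z[i]; ++n_t; }
  if (n_t < 2 * min_obs) return best;
  const double base = sum_t * sum_t / n_t;
  for (int j = 0; j < p; ++j) {
    double sum_l = 0.0;
    int n_l = 0;
    int prev_i = -1;
    const std::vector<int>& ord = order[j];
    for (size_t k = 0; k < ord.size(); ++k) {
      const int i = ord[k];
      if (member[i] != node_id) continue;
      if (prev_i >= 0) {
        const double x_prev = X(prev_i, j), x_cur = X(i, j);
        if (x_cur > x_prev && n_l >= min_obs && (n_t - n_l) >= min_obs) {
          const double sum_r = sum_t - sum_l;
          const double imp =
              sum_l * sum_l / n_l + sum_r * sum_r / (n_t - n_l) - base;
          if (imp > best.improve + kEps) {
            best.var = j;
            best.split = 0.5 * (x_prev + x_cur);
            best.improve = imp;
          }
        }
      }
      sum_l += z[i];
      ++n_l;
      prev_i = i;
    }
  }
  return best;
}

// Node layout in the per-tree matrix (one row per node):
//   0 var   (0-based split variable; -1 for a leaf)
//   1 split (threshold; x <= split goes left)
//   2 left  (row index of left child, -1 for leaf)
//   3 right (row index of right child)
//   4 value (Newton leaf value; 0 for internal)
//   5 improve (SSE reduction of the split; 0 for leaf)
//   6 n     (in-bag rows in the node)
struct TreeNode {
  int var = -1;
  double split = 0.0;
  int left = -1, right = -1;
  double value = 0.0;
  double improve = 0.0;
  int n = 0;
};

inline int descend(const std::vector<TreeNode>& nodes,
                   const NumericMatrix& X, int row) {
  int id = 0;
  while (nodes[id].var >= 0)
    id = (X(row, nodes[id].var) <= nodes[id].split) ? nodes[id].left
                                                    : nodes[id].right;
  return id;
}

inline int descend_mat(const NumericMatrix& tree,
                       const NumericMatrix& X, int row) {
  int id = 0;
  while (tree(id, 0) >= 0)
    id = (X(row, (int)tree(id, 0)) <= tree(id, 1)) ? (int)tree(id, 2)
                                                   : (int)tree(id, 3);
  return id;
}

}  // namespace

// Fit one boosted ensemble. Uses R's RNG (seed via set.seed on the R side).
// Optionally tracks held-out deviance/predictions every `record_every` trees.
// [[Rcpp::export]]
List bct_boost_cpp(NumericMatrix X, NumericVector y, int n_trees,
                   double shrinkage, double bag_fraction, int max_splits,
                   int min_obs,
                   Nullable<NumericMatrix> X_valid_ = R_NilValue,
                   Nullable<NumericVector> y_valid_ = R_NilValue,
                   int record_every = 50, bool keep_trees = true,
                   bool record_pred = false) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) must equal nrow(X)");

  NumericMatrix X_valid;
  NumericVector y_valid;
  bool has_valid = false;
  if (X_valid_.isNotNull()) {
    X_valid = as<NumericMatrix>(X_valid_);
    has_valid = true;
    if (y_valid_.isNotNull()) y_valid = as<NumericVector>(y_valid_);
  }
  const int nv = has_valid ? X_valid.nrow() : 0;

  // Presort feature orders once.
  std::vector<std::vector<int> > order(p);
  for (int j = 0; j < p; ++j) {
    order[j].resize(n);
    for (int i = 0; i < n; ++i) order[j][i] = i;
    const int jj = j;
    std::stable_sort(order[j].begin(), order[j].end(),
                     [&X, jj](int a, int b) { return X(a, jj) < X(b, jj); });
  }

  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  ybar = std::min(1.0 - kEps, std::max(kEps, ybar));
  const double f0 = std::log(ybar / (1.0 - ybar));

  std::vector<double> f(n, f0), prob(n, ybar);
  std::vector<double> fv(nv, f0), pv(nv, ybar);
  std::vector<double> z(n), h(n);
  std::vector<int> member(n);
  std::vector<int> bag(n);
  const int n_bag = std::max(1, (int)std::floor(bag_fraction * n + 0.5));

  NumericVector importance(p);
  std::vector<double> valid_dev;
  std::vector<int> checkpoints;
  std::vector<std::vector<double> > valid_preds;

  List trees(keep_trees ? n_trees : 0);

  for (int t = 0; t < n_trees; ++t) {
    // bag: first n_bag of a partial Fisher-Yates permutation
    for (int i = 0; i < n; ++i) bag[i] = i;
    for (int i = 0; i < n_bag; ++i) {
      int j = i + (int)std::floor(unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(bag[i], bag[j]);
    }
    std::fill(member.begin(), member.end(), -1);
    for (int i = 0; i < n_bag; ++i) member[bag[i]] = 0;

    for (int i = 0; i < n; ++i) {
      z[i] = y[i] - prob[i];
      h[i] = std::max(kEps, prob[i] * (1.0 - prob[i]));
    }

    // best-first tree growth with a split budget
    std::vector<TreeNode> nodes(1);
    nodes[0].n = n_bag;
    std::vector<SplitInfo> cand(1);
    cand[0] = best_split(X, order, z, member, 0, min_obs);

    for (int s = 0; s < max_splits; ++s) {
      int pick = -1;
      double best_imp = kEps;
      for (size_t c = 0; c < cand.size(); ++c)
        if (nodes[c].var < 0 && cand[c].var >= 0 &&
            cand[c].improve > best_imp) {
          best_imp = cand[c].improve;
          pick = (int)c;
        }
      if (pick < 0) break;
      const int L = (int)nodes.size(), R = L + 1;
      nodes[pick].var = cand[pick].var;
      nodes[pick].split = cand[pick].split;
      nodes[pick].left = L;
      nodes[pick].right = R;
      nodes[pick].improve = cand[pick].improve;
      importance[nodes[pick].var] += cand[pick].improve;
      nodes.push_back(TreeNode());
      nodes.push_back(TreeNode());
      int nL = 0, nR = 0;
      for (int i = 0; i < n; ++i)
        if (member[i] == pick) {
          if (X(i, nodes[pick].var) <= nodes[pick].split) {
            member[i] = L;
            ++nL;
          } else {
            member[i] = R;
            ++nR;
          }
        }
      nodes[L].n = nL;
      nodes[R].n = nR;
      cand.push_back(best_split(X, order, z, member, L, min_obs));
      cand.push_back(best_split(X, order, z, member, R, min_obs));
    }

    // Newton leaf values from in-bag rows
    std::vector<double> num(nodes.size(), 0.0), den(nodes.size(), 0.0);
    for (int i = 0; i < n; ++i)
      if (member[i] >= 0) {
        num[member[i]] += z[i];
        den[member[i]] += h[i];
      }
    for (size_t id = 0; id < nodes.size(); ++id)
      if (nodes[id].var < 0) nodes[id].value = num[id] / (den[id] + kEps);

    // update train (all rows) and validation scores
    for (int i = 0; i < n; ++i) {
      f[i] += shrinkage * nodes[descend(nodes, X, i)].value;
      prob[i] = logistic(f[i]);
    }
    for (int i = 0; i < nv; ++i) {
      fv[i] += shrinkage * nodes[descend(nodes, X_valid, i)].value;
      pv[i] = logistic(fv[i]);
    }

    if (keep_trees) {
      NumericMatrix tm(nodes.size(), 7);
      for (size_t id = 0; id < nodes.size(); ++id) {
        tm(id, 0) = nodes[id].var;
        tm(id, 1) = nodes[id].split;
        tm(id, 2) = nodes[id].left;
        tm(id, 3) = nodes[id].right;
        tm(id, 4) = nodes[id].value;
        tm(id, 5) = nodes[id].improve;
        tm(id, 6) = nodes[id].n;
      }
      trees[t] = tm;
    }

    if (has_valid && record_every > 0 && ((t + 1) % record_every == 0)) {
      checkpoints.push_back(t + 1);
      if (y_valid.size() == nv) valid_dev.push_back(bern_dev(pv, y_valid));
      if (record_pred) valid_preds.push_back(pv);
    }
  }

  NumericVector train_p(n), valid_p(nv);
  for (int i = 0; i < n; ++i) train_p[i] = prob[i];
  for (int i = 0; i < nv; ++i) valid_p[i] = pv[i];

  NumericMatrix vp_mat(record_pred ? nv : 0,
                       record_pred ? (int)valid_preds.size() : 0);
  if (record_pred)
    for (size_t c = 0; c < valid_preds.size(); ++c)
      for (int i = 0; i < nv; ++i) vp_mat(i, c) = valid_preds[c][i];

  return List::create(
      _["trees"] = trees, _["intercept"] = f0, _["shrinkage"] = shrinkage,
      _["importance"] = importance, _["train_prob"] = train_p,
      _["valid_prob"] = valid_p, _["valid_dev"] = wrap(valid_dev),
      _["checkpoints"] = wrap(checkpoints), _["valid_pred"] = vp_mat);
}

// Predict probabilities from the first n_use trees of a fitted model.
// [[Rcpp::export]]
NumericVector bct_predict_cpp(List trees, double intercept, double shrinkage,
                              NumericMatrix X, int n_use = -1) {
  const int n = X.nrow();
  const int nt = trees.size();
  const int use = (n_use < 0 || n_use > nt) ? nt : n_use;
  NumericVector out(n);
  std::vector<double> f(n, intercept);
  for (int t = 0; t < use; ++t) {
    NumericMatrix tm = trees[t];
    for (int i = 0; i < n; ++i)
      f[i] += shrinkage * tm(descend_mat(tm, X, i), 4);
  }
  for (int i = 0; i < n; ++i) out[i] = logistic(f[i]);
  return out;
}
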