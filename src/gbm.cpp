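// Stagewise gradient boosting of shallow regression trees with
// squared-error loss, case weights and bagged subsampling.  Trees are
// grown best-first with a fixed number of splits (the "tree complexity" /
// interaction depth).  Randomness comes from R's RNG so everything is
// reproducible via set.seed() on the R side.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

struct SplitInfo {
  double gain = -1.0;
  int var = -1;
  double split = 0.0;
};

struct Leaf {
  std::vector<int> idx;
  SplitInfo best;
  int node = -1;  // index into the flat node arrays
};

static SplitInfo best_split(const NumericMatrix& X,
                            const std::vector<double>& r,
                            const NumericVector& w,
                            const std::vector<int>& idx, int min_obs) {
  const int p = X.ncol();
  const int m = (int)idx.size();
  SplitInfo best;
  if (m < 2 * min_obs) return best;
  double W = 0.0, S = 0.0;
  for (int t : idx) { W += w[t]; S += w[t] * r[t]; }
  if (W <= 0.0) return best;
  const double parent = S * S / W;
  std::vector<std::pair<double, int>> xv(m);
  for (int j = 0; j < p; ++j) {
    for (int t = 0; t < m; ++t) xv[t] = {X(idx[t], j), idx[t]};
    std::sort(xv.begin(), xv.end());
    double WL = 0.0, SL = 0.0;
    for (int t = 0; t < m - 1; ++t) {
      const int i = xv[t].second;
      WL += w[i];
      SL += w[i] * r[i];
      if (xv[t + 1].first <= xv[t].first) continue;  // not a value boundary
      const int nl = t + 1, nr = m - nl;
      if (nl < min_obs || nr < min_obs) continue;
      const double WR = W - WL, SR = S - SL;
      if (WL <= 0.0 || WR <= 0.0) continue;
      const double gain = SL * SL / WL + SR * SR / WR - parent;
      if (gain > best.gain) {
        best.gain = gain;
        best.var = j;
        best.split = 0.5 * (xv[t].first + xv[t + 1].first);
      }
    }
  }
  return best;
}

struct Tree {
  std::vector<int> var, left, right;
  std::vector<double> split, value;

  int add_leaf(double v) {
    var.push_back(-1);
    left.push_back(-1);
    right.push_back(-1);
    split.push_back(0.0);
    value.push_back(v);
    return (int)var.size() - 1;
  }

  double predict_row(const NumericMatrix& X, int i) const {
    int node = 0;
    while (var[node] >= 0)
      node = (X(i, var[node]) <= split[node]) ? left[node] : right[node];
    return value[node];
  }
};

static double wmean(const std::vector<double>& r, const NumericVector& w,
                    const std::vector<int>& idx) {
  double W = 0.0, S = 0.0;
  for (int t : idx) { W += w[t]; S += w[t] * r[t]; }
  return (W > 0.0) ? S / W : 0.0;
}

// grow one tree on the bagged rows with `depth` best-first splits
static Tree grow_tree(const NumericMatrix& X, const std::vector<double>& r,
                      const NumericVector& w, std::vector<int> bag,
                      int depth, int min_obs) {
  Tree tr;
  std::vector<Leaf> leaves;
  Leaf root;
  root.idx = std::move(bag);
  root.node = tr.add_leaf(wmean(r, w, root.idx));
  root.best = best_split(X, r, w, root.idx, min_obs);
  leaves.push_back(std::move(root));
  for (int s = 0; s < depth; ++s) {
    int pick = -1;
    double g = 1e-12;
    for (int l = 0; l < (int)leaves.size(); ++l)
      if (leaves[l].best.gain > g) { g = leaves[l].best.gain; pick = l; }
    if (pick < 0) break;
    Leaf& lf = leaves[pick];
    const int j = lf.best.var;
    const double cut = lf.best.split;
    Leaf lchild, rchild;
    for (int t : lf.idx)
      (X(t, j) <= cut ? lchild.idx : rchild.idx).push_back(t);
    tr.var[lf.node] = j;
    tr.split[lf.node] = cut;
    lchild.node = tr.add_leaf(wmean(r, w, lchild.idx));
    rchild.node = tr.add_leaf(wmean(r, w, rchild.idx));
    tr.left[lf.node] = lchild.node;
    tr.right[lf.node] = rchild.node;
    lchild.best = best_split(X, r, w, lchild.idx, min_obs);
    rchild.best = best_split(X, r, w, rchild.idx, min_obs);
    leaves[pick] = std::move(lchild);
    leaves.push_back(std::move(rchild));
  }
  return tr;
}

static List tree_to_list(const Tree& tr) {
  return List::create(_["var"] = IntegerVector(tr.var.begin(), tr.var.end()),
                      _["split"] = NumericVector(tr.split.begin(), tr.split.end()),
                      _["left"] = IntegerVector(tr.left.begin(), tr.left.end()),
                      _["right"] = IntegerVector(tr.right.begin(), tr.right.end()),
                      _["value"] = NumericVector(tr.value.begin(), tr.value.end()));
}

// [[Rcpp::export]]
List cpp_gbm_fit(NumericMatrix X, NumericVector y, NumericVector w,
                 NumericMatrix Xval, int n_trees, double shrinkage,
                 int interaction_depth, double bag_fraction, int min_obs,
                 int step_size, bool keep_trees) {
  const int n = X.nrow();
  const int nval = Xval.nrow();
  double W = 0.0, S = 0.0;
  for (int i = 0; i < n; ++i) { W += w[i]; S += w[i] * y[i]; }
  const double init = S / W;
  std::vector<double> F(n, init), Fval(nval, init), r(n);
  const int nb = std::max(2, (int)std::floor(bag_fraction * n));
  std::vector<int> pool(n);
  for (int i = 0; i < n; ++i) pool[i] = i;

  std::vector<int> checkpoints;
  for (int t = step_size; t < n_trees; t += step_size) checkpoints.push_back(t);
  checkpoints.push_back(n_trees);
  const int nck = (int)checkpoints.size();
  NumericMatrix val_staged(nval, nck);
  NumericVector train_dev(nck);
  List trees(keep_trees ? n_trees : 0);

  int ck = 0;
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) r[i] = y[i] - F[i];
    // partial Fisher-Yates bag draw (without replacement)
    for (int i = 0; i < nb; ++i) {
      int j = i + (int)(unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(pool[i], pool[j]);
    }
    std::vector<int> bag(pool.begin(), pool.begin() + nb);
    Tree tr = grow_tree(X, r, w, std::move(bag), interaction_depth, min_obs);
    for (int i = 0; i < n; ++i) F[i] += shrinkage * tr.predict_row(X, i);
    for (int i = 0; i < nval; ++i) Fval[i] += shrinkage * tr.predict_row(Xval, i);
    if (keep_trees) trees[t] = tree_to_list(tr);
    if (t + 1 == checkpoints[ck]) {
      double dev = 0.0;
      for (int i = 0; i < n; ++i)
        dev += w[i] * (y[i] - F[i]) * (y[i] - F[i]);
      train_dev[ck] = dev / W;
      for (int i = 0; i < nval; ++i) val_staged(i, ck) = Fval[i];
      ++ck;
    }
  }
  return List::create(_["init"] = init,
                      _["trees"] = trees,
                      _["checkpoints"] = IntegerVector(checkpoints.begin(), checkpoints.end()),
                      _["val_staged"] = val_staged,
                      _["train_dev"] = train_dev,
                      _["fitted"] = NumericVector(F.begin(), F.end()));
}

// [[Rcpp::export]]
NumericVector cpp_gbm_predict(List trees, double init, double shrinkage,
                              NumericMatrix X, int n_trees) {
  const int n = X.nrow();
  NumericVector out(n, init);
  const int nt = std::min((int)trees.size(), n_trees);
  for (int t = 0; t < nt; ++t) {
    List tl = trees[t];
    IntegerVector var = tl["var"], left = tl["left"], right = tl["right"];
    NumericVector split = tl["split"], value = tl["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (var[node] >= 0)
        node = (X(i, var[node]) <= split[node]) ? left[node] : right[node];
      out[i] += shrinkage * value[node];
    }
  }
  return out;
}
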