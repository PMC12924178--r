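#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Interventional Shapley values for binary regression trees.
//
// For one tree, one explained instance x and one background row z, the
// coalition value is f(S) = tree(h) with h taking features in S from x and
// the rest from z. Each leaf L contributes val_L * [A_L subset of S] *
// [B_L disjoint from S], where A_L are the features whose path conditions
// only x satisfies and B_L those only z satisfies (conjunction over
// repeated appearances of a feature on the path; a leaf whose path a
// feature satisfies for neither source is unreachable for every S).
// The Shapley value of such a conjunction game is closed-form, so a depth-
// first pass that only branches where x and z diverge computes exact
// values. Forests and background sets enter by linearity (averaging).

struct Tree {
  std::vector<int> left, right, feat;
  std::vector<double> split, value;
};

struct Coef {
  // P[a][b]: weight added to phi_i, i in A; Q[a][b]: weight subtracted
  // from phi_i, i in B (a = |A| >= 1 resp. b = |B| >= 1)
  std::vector<std::vector<double>> P, Q;
};

static double lchoose_(int n, int k) {
  return std::lgamma(n + 1.0) - std::lgamma(k + 1.0) - std::lgamma(n - k + 1.0);
}

static Coef make_coef(int n) {
  Coef c;
  c.P.assign(n + 1, std::vector<double>(n + 1, 0.0));
  c.Q.assign(n + 1, std::vector<double>(n + 1, 0.0));
  const double lfn = std::lgamma(n + 1.0);
  for (int a = 0; a <= n; ++a) {
    for (int b = 0; b + a <= n; ++b) {
      int m = n - a - b;
      if (a >= 1) {
        double s = 0.0;
        for (int k = 0; k <= m; ++k) {
          int sz = a - 1 + k;  // |S| with i added on top
          s += std::exp(lchoose_(m, k) + std::lgamma(sz + 1.0) +
                        std::lgamma(n - sz + 0.0) - lfn);
        }
        c.P[a][b] = s;
      }
      if (b >= 1) {
        double s = 0.0;
        for (int k = 0; k <= m; ++k) {
          int sz = a + k;  // |S| before i (in B) is added
          s += std::exp(lchoose_(m, k) + std::lgamma(sz + 1.0) +
                        std::lgamma(n - sz + 0.0) - lfn);
        }
        c.Q[a][b] = s;
      }
    }
  }
  return c;
}

// state per feature: 0 unconstrained, 1 satisfied by x only (in A),
// 2 satisfied by z only (in B)
static void dfs(const Tree& tr, int node, const double* x, const double* z,
                std::vector<int>& state, int nfeat, const Coef& cf,
                double* phi) {
  int f = tr.feat[node];
  if (f < 0) {  // leaf
    int a = 0, b = 0;
    for (int j = 0; j < nfeat; ++j) {
      if (state[j] == 1) ++a;
      else if (state[j] == 2) ++b;
    }
    if (a == 0 && b == 0) return;  // constant part, lives in the base value
    double val = tr.value[node];
    for (int j = 0; j < nfeat; ++j) {
      if (state[j] == 1) phi[j] += val * cf.P[a][b];
      else if (state[j] == 2) phi[j] -= val * cf.Q[a][b];
    }
    return;
  }
  bool xs = x[f] <= tr.split[node];
  bool zs = z[f] <= tr.split[node];
  if (xs == zs) {
    dfs(tr, xs ? tr.left[node] : tr.right[node], x, z, state, nfeat, cf, phi);
    return;
  }
  int old = state[f];
  int sL = xs ? 1 : 2;  // who satisfies the left (<=) condition
  int sR = 3 - sL;
  if (old == 0 || old == sL) {
    state[f] = sL;
    dfs(tr, tr.left[node], x, z, state, nfeat, cf, phi);
    state[f] = old;
  }
  if (old == 0 || old == sR) {
    state[f] = sR;
    dfs(tr, tr.right[node], x, z, state, nfeat, cf, phi);
    state[f] = old;
  }
}

static std::vector<Tree> build_trees(List trees) {
  std::vector<Tree> out(trees.size());
  for (int t = 0; t < trees.size(); ++t) {
    List tl = trees[t];
    IntegerVector L = tl["left"], R = tl["right"], F = tl["feat"];
    NumericVector S = tl["split"], V = tl["value"];
    Tree& tr = out[t];
    tr.left.assign(L.begin(), L.end());
    tr.right.assign(R.begin(), R.end());
    tr.feat.assign(F.begin(), F.end());
    tr.split.assign(S.begin(), S.end());
    tr.value.assign(V.begin(), V.end());
  }
  return out;
}

// [[Rcpp::export(name = ".forest_interventional_shap")]]
NumericMatrix forest_interventional_shap(List trees, NumericMatrix X,
                                         NumericMatrix B) {
  int nfeat = X.ncol();
  if (B.ncol() != nfeat) stop("X and B must have the same number of columns");
  std::vector<Tree> forest = build_trees(trees);
  Coef cf = make_coef(nfeat);
  int ni = X.nrow(), nb = B.nrow(), nt = forest.size();
  NumericMatrix phi(ni, nfeat);
  std::vector<double> xrow(nfeat), zrow(nfeat), acc(nfeat);
  std::vector<int> state(nfeat);
  for (int i = 0; i < ni; ++i) {
    for (int j = 0; j < nfeat; ++j) xrow[j] = X(i, j);
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int b = 0; b < nb; ++b) {
      for (int j = 0; j < nfeat; ++j) zrow[j] = B(b, j);
      for (int t = 0; t < nt; ++t) {
        std::fill(state.begin(), state.end(), 0);
        dfs(forest[t], 0, xrow.data(), zrow.data(), state, nfeat, cf,
            acc.data());
      }
    }
    double norm = 1.0 / (double(nb) * double(nt));
    for (int j = 0; j < nfeat; ++j) phi(i, j) = acc[j] * norm;
    Rcpp::checkUserInterrupt();
  }
  return phi;
}

// [[Rcpp::export(name = ".forest_predict_cpp")]]
NumericVector forest_predict_cpp(List trees, NumericMatrix X) {
  std::vector<Tree> forest = build_trees(trees);
  int ni = X.nrow(), nt = forest.size();
  NumericVector out(ni);
  for (int i = 0; i < ni; ++i) {
    double s = 0.0;
    for (int t = 0; t < nt; ++t) {
      const Tree& tr = forest[t];
      int node = 0;
      while (tr.feat[node] >= 0)
        node = X(i, tr.feat[node]) <= tr.split[node] ? tr.left[node]
                                                     : tr.right[node];
      s += tr.value[node];
    }
    out[i] = s / nt;
  }
  return out;
}
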