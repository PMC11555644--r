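// Greedy Bayesian classification tree for the window screen.
// Leaves carry Beta(1,1)-Binomial marginals of the case count; splits are
// "dosage <= c" indicators passed in as 0/1 matrices (one per threshold).
// A split is accepted only when the children's marginal likelihood plus
// the structural log-prior beats the leaf marginal; growth is greedy and
// depth-limited.  The permutation-null driver re-runs the growth for each
// permuted phenotype column.  Beta-function values are served from a
// cached lgamma table (integer arguments only).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct LgammaTable {
  std::vector<double> lg;
  explicit LgammaTable(int nmax) : lg(nmax + 3) {
    for (int i = 1; i < (int)lg.size(); ++i) lg[i] = std::lgamma((double)i);
  }
  // log B(n1 + 1, n0 + 1)
  inline double leaf(int n1, int n0) const {
    return lg[n1 + 1] + lg[n0 + 1] - lg[n1 + n0 + 2];
  }
};

static double grow(const std::vector<int> &idx, const int *y,
                   const IntegerMatrix &M0, const IntegerMatrix &M1,
                   int depth, int max_depth, int min_leaf,
                   double log_split_prior, const LgammaTable &tab) {
  const int n = (int)idx.size();
  int n1 = 0;
  for (int i = 0; i < n; ++i) n1 += y[idx[i]];
  const double leaf = tab.leaf(n1, n - n1);
  if (depth >= max_depth || n < 2 * min_leaf) return leaf;

  const int d = M0.ncol();
  double best_gain = 0.0;
  int best_j = -1, best_c = -1;
  for (int c = 0; c < 2; ++c) {
    const IntegerMatrix &M = (c == 0) ? M0 : M1;
    for (int j = 0; j < d; ++j) {
      const int *col = &M(0, j);
      int nl = 0, nl1 = 0;
      for (int i = 0; i < n; ++i) {
        const int r = idx[i];
        const int m = col[r];
        nl += m;
        nl1 += m & y[r];
      }
      const int nr = n - nl;
      if (nl < min_leaf || nr < min_leaf) continue;
      const int nr1 = n1 - nl1;
      const double gain = tab.leaf(nl1, nl - nl1) +
        tab.leaf(nr1, nr - nr1) + log_split_prior - leaf;
      if (gain > best_gain) { best_gain = gain; best_j = j; best_c = c; }
    }
  }
  if (best_j < 0) return leaf;
  const IntegerMatrix &M = (best_c == 0) ? M0 : M1;
  const int *col = &M(0, best_j);
  std::vector<int> left, right;
  left.reserve(n); right.reserve(n);
  for (int i = 0; i < n; ++i) {
    const int r = idx[i];
    if (col[r]) left.push_back(r); else right.push_back(r);
  }
  return grow(left, y, M0, M1, depth + 1, max_depth, min_leaf,
              log_split_prior, tab)
    + grow(right, y, M0, M1, depth + 1, max_depth, min_leaf,
           log_split_prior, tab)
    + log_split_prior;
}

// [[Rcpp::export]]
double cpp_grow_tree(IntegerVector y, IntegerMatrix M0, IntegerMatrix M1,
                     int max_depth, int min_leaf,
                     double log_split_prior) {
  const int n = y.size();
  LgammaTable tab(n);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  return grow(idx, INTEGER(y), M0, M1, 0, max_depth, min_leaf,
              log_split_prior, tab);
}

// One tree log-marginal per column of the permuted-phenotype matrix Y.
// [[Rcpp::export]]
NumericVector cpp_grow_tree_multi(IntegerMatrix Y, IntegerMatrix M0,
                                  IntegerMatrix M1, int max_depth,
                                  int min_leaf, double log_split_prior) {
  const int n = Y.nrow(), B = Y.ncol();
  LgammaTable tab(n);
  NumericVector out(B);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  for (int b = 0; b < B; ++b) {
    out[b] = grow(idx, &Y(0, b), M0, M1, 0, max_depth, min_leaf,
                  log_split_prior, tab);
  }
  return out;
}
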