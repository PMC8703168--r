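#include <Rcpp.h>
using namespace Rcpp;

// Traverse one randomForest tree (getTree(..., labelVar = FALSE) layout:
// columns 0..5 = left daughter, right daughter, split var, split point,
// status, prediction) for sample row i, optionally overriding one
// variable's value. Returns the predicted class index (1-based).
static inline int tree_pred(const NumericMatrix& tr, const NumericMatrix& x,
                            int i, int override_var, double override_val) {
  int node = 0;
  while ((int)tr(node, 4) != -1) {
    int v = (int)tr(node, 2) - 1;
    double xv = (v == override_var) ? override_val : x(i, v);
    node = (xv <= tr(node, 3)) ? (int)tr(node, 0) - 1 : (int)tr(node, 1) - 1;
  }
  return (int)tr(node, 5);
}

// Per-tree out-of-bag error before and after within-OOB permutation of
// each variable. Returns the per-tree baseline OOB error and the matrix
// of error increases (trees x variables). Uses R's RNG for the
// permutations, so results are reproducible under set.seed().
// [[Rcpp::export(name = ".vim_forest_cpp")]]
List vim_forest_cpp(List trees, NumericMatrix x, IntegerVector y,
                    IntegerMatrix inbag) {
  int ntree = trees.size(), n = x.nrow(), p = x.ncol();
  NumericVector err1(ntree);
  NumericMatrix derr(ntree, p);
  std::vector<int> oob, base, perm;
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix tr = trees[t];
    oob.clear();
    for (int i = 0; i < n; ++i)
      if (inbag(i, t) == 0) oob.push_back(i);
    int m = (int)oob.size();
    if (m == 0) { err1[t] = NA_REAL; continue; }
    base.assign(m, 0);
    int wrong = 0;
    for (int j = 0; j < m; ++j) {
      base[j] = tree_pred(tr, x, oob[j], -1, 0.0);
      if (base[j] != y[oob[j]]) ++wrong;
    }
    err1[t] = (double)wrong / m;
    perm.resize(m);
    for (int v = 0; v < p; ++v) {
      for (int j = 0; j < m; ++j) perm[j] = j;
      for (int j = m - 1; j > 0; --j) {
        int k = (int)(unif_rand() * (j + 1));
        if (k > j) k = j;
        std::swap(perm[j], perm[k]);
      }
      int wrong2 = 0;
      for (int j = 0; j < m; ++j) {
        double val = x(oob[perm[j]], v);
        if (tree_pred(tr, x, oob[j], v, val) != y[oob[j]]) ++wrong2;
      }
      derr(t, v) = (double)wrong2 / m - err1[t];
    }
  }
  return List::create(_["err1"] = err1, _["derr"] = derr);
}
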