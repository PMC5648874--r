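#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Group-average (UPGMA) agglomeration over a dense dissimilarity matrix.
//
// Between-cluster state is kept as SUMS of pairwise leaf dissimilarities,
// so the merge height is sum / (size_i * size_j) -- the exact arithmetic
// mean of all between-cluster leaf pairs, and sums update additively when
// clusters merge. Ties in the minimum height are broken by the
// lexicographically smallest (min-label, max-label) pair, a cluster's
// label being the smallest leaf label it contains. Deterministic.
//
// Returns an hclust-style merge matrix (negative = leaf) and heights.
// [[Rcpp::export]]
List upgma_cpp(NumericMatrix d, CharacterVector labels) {
  const int n = d.nrow();
  if (n < 2) stop("need at least 2 leaves");
  std::vector<double> S((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double v = d(i, j);
      if (!R_finite(v)) stop("non-finite dissimilarity in input matrix");
      S[(size_t)i * n + j] = v;
    }
  std::vector<int> id(n), sz(n, 1);
  std::vector<std::string> lab(n);
  std::vector<bool> active(n, true);
  for (int i = 0; i < n; ++i) { id[i] = -(i + 1); lab[i] = as<std::string>(labels[i]); }

  IntegerMatrix merge(n - 1, 2);
  NumericVector height(n - 1);

  for (int step = 0; step < n - 1; ++step) {
    double best = R_PosInf;
    int bi = -1, bj = -1;
    const std::string *bl = nullptr, *bh = nullptr;
    for (int i = 0; i < n; ++i) {
      if (!active[i]) continue;
      for (int j = i + 1; j < n; ++j) {
        if (!active[j]) continue;
        double h = S[(size_t)i * n + j] / ((double)sz[i] * sz[j]);
        bool take = false;
        if (h < best) take = true;
        else if (h == best) {
          const std::string &lo = lab[i] < lab[j] ? lab[i] : lab[j];
          const std::string &hi = lab[i] < lab[j] ? lab[j] : lab[i];
          if (lo < *bl || (lo == *bl && hi < *bh)) take = true;
        }
        if (take) {
          best = h; bi = i; bj = j;
          bl = lab[bi] < lab[bj] ? &lab[bi] : &lab[bj];
          bh = lab[bi] < lab[bj] ? &lab[bj] : &lab[bi];
        }
      }
    }
    // hclust convention: leaves (negative codes) listed before merged
    // clusters; within the same sign, smaller code first
    int a = id[bi], b = id[bj];
    if ((a < 0) != (b < 0)) { if (b < 0) std::swap(a, b); }
    else if (a > b) std::swap(a, b);
    merge(step, 0) = a;
    merge(step, 1) = b;
    height[step] = best;
    for (int k = 0; k < n; ++k) {
      if (!active[k] || k == bi || k == bj) continue;
      double s = S[(size_t)bi * n + k] + S[(size_t)bj * n + k];
      S[(size_t)bi * n + k] = s;
      S[(size_t)k * n + bi] = s;
    }
    sz[bi] += sz[bj];
    if (lab[bj] < lab[bi]) lab[bi] = lab[bj];
    id[bi] = step + 1;
    active[bj] = false;
  }
  return List::create(_["merge"] = merge, _["height"] = height);
}
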