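#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Bit-packed presence profiles: one bitset per cell over the species axis.
// Pairwise similarity then reduces to popcounts of ANDed words.

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

static double pair_sim(const uint64_t *ci, const uint64_t *cj, int nw,
                       int ri, int rj, int index) {
  int a = 0;
  for (int w = 0; w < nw; ++w) a += popcount64(ci[w] & cj[w]);
  int b = ri - a, c = rj - a;
  switch (index) {
  case 0: { int den = a + b + c; return den ? (double)a / den : 1.0; }          // jaccard
  case 1: { int den = 2 * a + b + c; return den ? 2.0 * a / den : 1.0; }        // sorensen
  default: { int m = b < c ? b : c; return (a + m) ? (double)a / (a + m) : 1.0; } // betasim
  }
}

static void pack_cells(const std::vector<int> &rowstart,
                       const std::vector<int> &cells_of_sp,
                       int nsp, int ncell, int nw,
                       std::vector<uint64_t> &bits, std::vector<int> &rich) {
  std::fill(bits.begin(), bits.end(), 0ULL);
  std::fill(rich.begin(), rich.end(), 0);
  for (int s = 0; s < nsp; ++s)
    for (int k = rowstart[s]; k < rowstart[s + 1]; ++k) {
      int c = cells_of_sp[k];
      bits[(size_t)c * nw + (s >> 6)] |= (1ULL << (s & 63));
      ++rich[c];
    }
}

static void sorted_profile(const std::vector<uint64_t> &bits,
                           const std::vector<int> &rich,
                           int ncell, int nw, int index,
                           std::vector<double> &prof) {
  int k = 0;
  for (int i = 0; i < ncell; ++i)
    for (int j = i + 1; j < ncell; ++j)
      prof[k++] = pair_sim(&bits[(size_t)i * nw], &bits[(size_t)j * nw], nw,
                           rich[i], rich[j], index);
  std::sort(prof.begin(), prof.end());
}

// SIMPROF permutation core for one group of cells.
//
// X: binary species x cells matrix restricted to the group. Each species'
// presences are shuffled independently across the cells (row-wise
// permutation preserving the species' cell count). Two independent
// permutation sets of size n_perm are drawn with R's RNG: the first gives
// the mean ordered similarity profile, the second the null distribution of
// pi = sum_k |s_(k) - mean_(k)|. p uses the add-one estimator.
// index: 0 = jaccard, 1 = sorensen, 2 = betasim.
// [[Rcpp::export]]
List simprof_core(IntegerMatrix X, int n_perm, int index) {
  const int nsp = X.nrow(), ncell = X.ncol();
  if (ncell < 3) stop("SIMPROF needs at least 3 cells");
  const int nw = (nsp + 63) / 64;
  const int npair = ncell * (ncell - 1) / 2;

  // sparse row layout: cells occupied by each species
  std::vector<int> rowstart(nsp + 1, 0), cells_of_sp;
  for (int s = 0; s < nsp; ++s) {
    for (int c = 0; c < ncell; ++c) if (X(s, c)) cells_of_sp.push_back(c);
    rowstart[s + 1] = (int)cells_of_sp.size();
  }

  std::vector<uint64_t> bits((size_t)ncell * nw);
  std::vector<int> rich(ncell);
  std::vector<double> obs(npair), prof(npair), meanprof(npair, 0.0);

  pack_cells(rowstart, cells_of_sp, nsp, ncell, nw, bits, rich);
  sorted_profile(bits, rich, ncell, nw, index, obs);

  // row-wise shuffle: draw k distinct cells for a k-cell species by
  // partial Fisher-Yates over a reusable index vector
  std::vector<int> idx(ncell), perm_cells(cells_of_sp.size());
  std::vector<int> ps(rowstart);
  auto shuffle_rows = [&]() {
    for (int s = 0; s < nsp; ++s) {
      int k = rowstart[s + 1] - rowstart[s];
      for (int c = 0; c < ncell; ++c) idx[c] = c;
      for (int t = 0; t < k; ++t) {
        int r = t + (int)(unif_rand() * (ncell - t));
        if (r >= ncell) r = ncell - 1;
        std::swap(idx[t], idx[r]);
        perm_cells[rowstart[s] + t] = idx[t];
      }
    }
  };

  for (int p = 0; p < n_perm; ++p) {
    shuffle_rows();
    pack_cells(ps, perm_cells, nsp, ncell, nw, bits, rich);
    sorted_profile(bits, rich, ncell, nw, index, prof);
    for (int k = 0; k < npair; ++k) meanprof[k] += prof[k];
  }
  for (int k = 0; k < npair; ++k) meanprof[k] /= n_perm;

  double pi = 0.0;
  for (int k = 0; k < npair; ++k) pi += std::fabs(obs[k] - meanprof[k]);

  int ge = 0;
  NumericVector null_pi(n_perm);
  for (int p = 0; p < n_perm; ++p) {
    shuffle_rows();
    pack_cells(ps, perm_cells, nsp, ncell, nw, bits, rich);
    sorted_profile(bits, rich, ncell, nw, index, prof);
    double s = 0.0;
    for (int k = 0; k < npair; ++k) s += std::fabs(prof[k] - meanprof[k]);
    null_pi[p] = s;
    if (s >= pi) ++ge;
  }
  double pval = (1.0 + ge) / (1.0 + n_perm);
  return List::create(_["pi"] = pi, _["p_value"] = pval,
                      _["null_pi"] = null_pi,
                      _["mean_profile"] = NumericVector(meanprof.begin(), meanprof.end()),
                      _["observed_profile"] = NumericVector(obs.begin(), obs.end()));
}
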