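#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Agglomerative hierarchical clustering by the Lance-Williams recurrence.
// method: 0 = single, 1 = complete, 2 = average (UPGMA), 3 = ward.D2
// (Murtagh-Legendre: updates on squared dissimilarities, merge heights
// reported on the original distance scale).
// Ties on the minimal distance are broken deterministically: the pair with
// the lexicographically smallest (i, j) position indices wins.
// [[Rcpp::export]]
List cpp_linkage(NumericMatrix d0, int method) {
  const int n = d0.nrow();
  if (n < 2) stop("need at least two leaves");
  std::vector<double> d(n * (size_t)n);
  const bool squared = (method == 3);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) {
      double v = d0(i, j);
      d[i + (size_t)n * j] = squared ? v * v : v;
    }
  std::vector<int> size(n, 1), id(n);
  std::vector<bool> active(n, true);
  for (int i = 0; i < n; ++i) id[i] = -(i + 1);
  IntegerMatrix merge(n - 1, 2);
  NumericVector height(n - 1);
  for (int m = 0; m < n - 1; ++m) {
    double best = R_PosInf;
    int bi = -1, bj = -1;
    // scan column-contiguously (i inner) for cache locality; the
    // comparison keeps the (i, j)-lexicographic tie-break
    for (int j = 1; j < n; ++j) {
      if (!active[j]) continue;
      const double* col = &d[(size_t)n * j];
      for (int i = 0; i < j; ++i) {
        if (!active[i]) continue;
        double v = col[i];
        if (v < best ||
            (v == best && (i < bi || (i == bi && j < bj)))) {
          best = v; bi = i; bj = j;
        }
      }
    }
    merge(m, 0) = id[bi];
    merge(m, 1) = id[bj];
    height[m] = squared ? std::sqrt(best) : best;
    const double ni = size[bi], nj = size[bj];
    for (int k = 0; k < n; ++k) {
      if (!active[k] || k == bi || k == bj) continue;
      double dik = d[std::min(bi, k) + (size_t)n * std::max(bi, k)];
      double djk = d[std::min(bj, k) + (size_t)n * std::max(bj, k)];
      double nd;
      switch (method) {
        case 0: nd = std::min(dik, djk); break;
        case 1: nd = std::max(dik, djk); break;
        case 2: nd = (ni * dik + nj * djk) / (ni + nj); break;
        default: {
          const double nk = size[k];
          nd = ((ni + nk) * dik + (nj + nk) * djk - nk * best) /
               (ni + nj + nk);
        }
      }
      d[std::min(bi, k) + (size_t)n * std::max(bi, k)] = nd;
    }
    size[bi] += size[bj];
    active[bj] = false;
    id[bi] = m + 1;
  }
  return List::create(_["merge"] = merge, _["height"] = height);
}
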