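#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Weighted Kolmogorov-Smirnov running-sum enrichment score.
// w: per-rank hit increments |score|^exponent for the full ranked list
// (length L, descending rank order); pos: sorted 1-based hit positions.
// Hits step up by w[pos]/sum(w[pos]) (equal steps if that sum is 0),
// misses step down by 1/(L - k). ES is the signed maximum deviation of
// the walk from 0; a |sup| == |inf| tie (within 1e-9, so that analytic
// ties are not decided by accumulated rounding) returns the positive
// extremum. Must stay in lockstep with the R reference in gsea_es().
static double es_core(const NumericVector& w, const std::vector<int>& pos) {
  const int L = w.size();
  const int k = (int) pos.size();
  double NR = 0.0;
  for (int i = 0; i < k; ++i) NR += w[pos[i] - 1];
  const bool unweighted = !(NR > 0.0);
  const double miss = (L > k) ? 1.0 / (double)(L - k) : 0.0;
  double cum = 0.0, sup = 0.0, inf = 0.0;
  for (int i = 0; i < k; ++i) {
    const double wi = unweighted ? 1.0 / k : w[pos[i] - 1] / NR;
    const double bottom = cum - (double)(pos[i] - 1 - i) * miss;
    const double top = bottom + wi;
    cum += wi;
    if (top > sup) sup = top;
    if (bottom < inf) inf = bottom;
  }
  return (sup + inf >= -1e-9) ? sup : inf;
}

// [[Rcpp::export(name = ".es_from_positions")]]
double es_from_positions(NumericVector w, IntegerVector positions) {
  std::vector<int> pos(positions.begin(), positions.end());
  std::sort(pos.begin(), pos.end());
  return es_core(w, pos);
}

// ES for each column of a (k x n_sets) matrix of 1-based positions;
// used by the exact-enumeration p-value backend.
// [[Rcpp::export(name = ".es_for_sets")]]
NumericVector es_for_sets(NumericVector w, IntegerMatrix sets) {
  const int k = sets.nrow(), n = sets.ncol();
  NumericVector out(n);
  std::vector<int> pos(k);
  for (int s = 0; s < n; ++s) {
    for (int i = 0; i < k; ++i) pos[i] = sets(i, s);
    std::sort(pos.begin(), pos.end());
    out[s] = es_core(w, pos);
  }
  return out;
}

// ES of n_perm random size-k gene sets drawn uniformly without
// replacement from the L-gene universe. Uses R's RNG (partial
// Fisher-Yates), so results are reproducible under set.seed().
// [[Rcpp::export(name = ".es_random_sets")]]
NumericVector es_random_sets(NumericVector w, int k, int n_perm) {
  const int L = w.size();
  if (k < 1 || k > L) stop("query size out of range");
  NumericVector out(n_perm);
  std::vector<int> idx(L);
  for (int i = 0; i < L; ++i) idx[i] = i + 1;
  std::vector<int> pos(k);
  GetRNGstate();
  for (int p = 0; p < n_perm; ++p) {
    for (int j = 0; j < k; ++j) {
      int r = j + (int) std::floor(unif_rand() * (double)(L - j));
      if (r >= L) r = L - 1;
      std::swap(idx[j], idx[r]);
      pos[j] = idx[j];
    }
    std::sort(pos.begin(), pos.end());
    out[p] = es_core(w, pos);
  }
  PutRNGstate();
  return out;
}
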