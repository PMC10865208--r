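#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Feature-wise diff on min-max-normalized values; a pair with a missing
// entry contributes the feature's mean observed diff (md). Xt is the
// transposed data (features x instances) so one instance's features are
// contiguous in memory.
static inline double fdiff(const NumericMatrix& Xt, int i, int j, int f,
                           const NumericVector& md) {
  double a = Xt(f, i), b = Xt(f, j);
  if (NumericVector::is_na(a) || NumericVector::is_na(b)) return md[f];
  return std::fabs(a - b);
}

// Multiclass ReliefF weight accumulation. Xt: M x n matrix (features in
// rows) already scaled so per-feature diffs lie in [0, 1] (constant
// features are all-zero rows). y: 0-based class indices; sample_idx:
// 0-based instances to iterate (m = n passes 0..n-1); prior: class
// frequencies over all n columns. uniform = true averages miss classes
// equally, otherwise each miss class c is weighted
// prior[c] / (1 - prior[class(i)]).
// [[Rcpp::export]]
NumericVector relieff_core(NumericMatrix Xt, IntegerVector y, int k,
                           IntegerVector sample_idx, NumericVector md,
                           NumericVector prior, bool uniform) {
  const int n = Xt.ncol(), M = Xt.nrow(), m = sample_idx.size();
  const int C = prior.size();
  std::vector< std::vector<int> > members(C);
  for (int j = 0; j < n; ++j) members[y[j]].push_back(j);

  NumericVector W(M);
  std::vector<double> d(n);
  std::vector<double> hitmean(M), missacc(M), tmp(M);
  std::vector<int> cand;

  for (int s = 0; s < m; ++s) {
    const int i = sample_idx[s];
    const int ci = y[i];
    const double* xi = &Xt(0, i);
    for (int j = 0; j < n; ++j) {
      const double* xj = &Xt(0, j);
      double dd = 0.0;
      for (int f = 0; f < M; ++f) {
        const double a = xi[f], b = xj[f];
        dd += (ISNAN(a) || ISNAN(b)) ? md[f] : std::fabs(a - b);
      }
      d[j] = dd;
    }
    std::fill(hitmean.begin(), hitmean.end(), 0.0);
    std::fill(missacc.begin(), missacc.end(), 0.0);
    int nmiss_present = 0;
    for (int c = 0; c < C; ++c) {
      cand.clear();
      for (size_t t = 0; t < members[c].size(); ++t) {
        if (members[c][t] != i) cand.push_back(members[c][t]);
      }
      if (cand.empty()) continue;
      const int kc = std::min<int>(k, (int)cand.size());
      std::partial_sort(cand.begin(), cand.begin() + kc, cand.end(),
                        [&](int a, int b) {
                          if (d[a] != d[b]) return d[a] < d[b];
                          return a < b;  // deterministic: index breaks ties
                        });
      std::fill(tmp.begin(), tmp.end(), 0.0);
      for (int t = 0; t < kc; ++t) {
        const int j = cand[t];
        for (int f = 0; f < M; ++f) tmp[f] += fdiff(Xt, i, j, f, md);
      }
      for (int f = 0; f < M; ++f) tmp[f] /= kc;
      if (c == ci) {
        for (int f = 0; f < M; ++f) hitmean[f] = tmp[f];
      } else {
        ++nmiss_present;
        const double w = uniform ? 1.0 : prior[c] / (1.0 - prior[ci]);
        for (int f = 0; f < M; ++f) missacc[f] += w * tmp[f];
      }
    }
    if (uniform && nmiss_present > 0) {
      for (int f = 0; f < M; ++f) missacc[f] /= nmiss_present;
    }
    for (int f = 0; f < M; ++f) W[f] += missacc[f] - hitmean[f];
  }
  for (int f = 0; f < M; ++f) W[f] /= m;
  return W;
}
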