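#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Smith-Waterman local alignment score with affine gaps.
// Sequences are 0-based indices into the substitution matrix; a gap of
// length L costs gap_open + L * gap_extend. Score floored at 0 (empty
// alignment).
static double sw_core(const int *a, int n, const int *b, int m,
                      const NumericMatrix &sub, double go, double ge) {
  if (n == 0 || m == 0) return 0.0;
  const double NEG = -1e300;
  std::vector<double> H(m + 1, 0.0), F(m + 1, NEG), cur(m + 1, 0.0);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double E = NEG;
    cur[0] = 0.0;
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      E = std::max(E - ge, cur[j - 1] - go - ge);
      F[j] = std::max(F[j] - ge, H[j] - go - ge);
      double h = H[j - 1] + sub(ai, b[j - 1]);
      h = std::max(h, E);
      h = std::max(h, F[j]);
      h = std::max(h, 0.0);
      cur[j] = h;
      if (h > best) best = h;
    }
    std::swap(H, cur);
  }
  return best;
}

// [[Rcpp::export]]
double cpp_sw_score(IntegerVector a, IntegerVector b, NumericMatrix sub,
                    double gap_open, double gap_extend) {
  return sw_core(a.begin(), a.size(), b.begin(), b.size(), sub,
                 gap_open, gap_extend);
}

// [[Rcpp::export]]
NumericVector cpp_sw_scores(IntegerVector q, List subjects, NumericMatrix sub,
                            double gap_open, double gap_extend) {
  const int ns = subjects.size();
  NumericVector out(ns);
  for (int s = 0; s < ns; ++s) {
    IntegerVector b = subjects[s];
    out[s] = sw_core(q.begin(), q.size(), b.begin(), b.size(), sub,
                     gap_open, gap_extend);
  }
  return out;
}
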