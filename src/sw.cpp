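#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman / Gotoh) over a discretized
// column-state alphabet. s1, s2 are 1-based state indices into subst.
// A gap of length g costs gap_open + g * gap_extend.
// [[Rcpp::export]]
int sw_score_cpp(IntegerVector s1, IntegerVector s2, IntegerMatrix subst,
                 int gap_open, int gap_extend) {
  const int n = s1.size(), m = s2.size();
  if (n == 0 || m == 0) return 0;
  const int NEG = -1000000000;
  std::vector<int> H(m + 1, 0), E(m + 1, NEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int Hdiag = 0, F = NEG, Hij = 0;  // H[i][0] = 0 (local)
    const int a = s1[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(E[j] - gap_extend, H[j] - gap_open - gap_extend);
      F = std::max(F - gap_extend, Hij - gap_open - gap_extend);
      int diag = Hdiag + subst(a, s2[j - 1] - 1);
      Hdiag = H[j];
      Hij = std::max(std::max(0, diag), std::max(E[j], F));
      H[j] = Hij;
      if (Hij > best) best = Hij;
    }
  }
  return best;
}
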