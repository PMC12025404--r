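#include <Rcpp.h>
using namespace Rcpp;

// Template-match counting for sample entropy.
//
// Counts, under the Chebyshev metric with absolute tolerance r:
//   Cm  = unordered pairs (i < j) of m-dimensional embedding vectors
//         with distance <= r, among the M = n - m + 1 vectors;
//   Cm1 = the same among the M - 1 vectors of dimension m + 1.
//
// A pair matching at length m + 1 necessarily matches at length m, so the
// (m+1)-count is accumulated inside the m-loop restricted to i, j < M - 1:
// one pass over all pairs with early exit on the first out-of-tolerance
// coordinate. O(M^2 m) worst case, far less in practice.
// [[Rcpp::export(name = ".sampen_counts_cpp")]]
List sampen_counts_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const int M = n - m + 1;       // number of m-dimensional vectors
  if (M < 2)
    stop("series too short for embedding dimension m");
  const double *v = REAL(x);
  double Cm = 0.0, Cm1 = 0.0;
  for (int i = 0; i < M - 1; ++i) {
    for (int j = i + 1; j < M; ++j) {
      bool match_m = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(v[i + k] - v[j + k]) > r) { match_m = false; break; }
      }
      if (!match_m) continue;
      Cm += 1.0;
      // extend to m+1 when both vectors exist at that length
      if (j < M - 1 && std::fabs(v[i + m] - v[j + m]) <= r)
        Cm1 += 1.0;
    }
  }
  return List::create(_["C_m"] = Cm, _["C_m1"] = Cm1,
                      _["M"] = M, _["M1"] = M - 1);
}
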