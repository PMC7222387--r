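#include <Rcpp.h>
using namespace Rcpp;

// Meuwissen & Luo (1992) recursion for inbreeding coefficients and
// Mendelian-sampling variances. Parents are 0-based indices into the
// topologically sorted pedigree, -1 for unknown. Unknown parents use the
// F = -1 convention so that d_i = 0.5 - 0.25 (F_s + F_d) covers all cases
// (both unknown -> 1, one unknown -> 0.75 - 0.25 F).
// [[Rcpp::export]]
List inbreeding_ml(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericVector F(n), D(n);
  std::vector<double> L(n, 0.0);
  std::vector<bool> inlist(n, false);

  for (int i = 0; i < n; ++i) {
    double Fs = (sire[i] >= 0) ? F[sire[i]] : -1.0;
    double Fd = (dam[i]  >= 0) ? F[dam[i]]  : -1.0;
    D[i] = 0.5 - 0.25 * (Fs + Fd);
    if (sire[i] < 0 || dam[i] < 0) {
      F[i] = 0.0;
      continue;
    }
    // accumulate a_ii - 1 by tracing ancestors of i in decreasing index order
    double fi = -1.0;
    L[i] = 1.0;
    inlist[i] = true;
    for (int j = i; j >= 0; --j) {
      if (!inlist[j]) continue;
      double lj = L[j];
      int s = sire[j], d = dam[j];
      if (s >= 0) { L[s] += 0.5 * lj; inlist[s] = true; }
      if (d >= 0) { L[d] += 0.5 * lj; inlist[d] = true; }
      fi += lj * lj * D[j];
      L[j] = 0.0;
      inlist[j] = false;
    }
    F[i] = fi;
  }
  return List::create(_["F"] = F, _["D"] = D);
}

// Dense numerator relationship matrix by the tabular method.
// Requires topological order (parents before offspring).
// [[Rcpp::export]]
NumericMatrix tabular_A(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i], d = dam[i];
    for (int j = 0; j < i; ++j) {
      double v = 0.0;
      if (s >= 0) v += 0.5 * A(j, s);
      if (d >= 0) v += 0.5 * A(j, d);
      A(j, i) = v;
      A(i, j) = v;
    }
    double asd = (s >= 0 && d >= 0) ? A(s, d) : 0.0;
    A(i, i) = 1.0 + 0.5 * asd;
  }
  return A;
}
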