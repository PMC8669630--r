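#include <Rcpp.h>
#include <cmath>

// Hypergeometric upper-tail log-probabilities computed in log-space.
//
// For each input row, returns log(P(X >= f)) where X counts focus elements
// in a draw of s from a universe of N containing G focus elements.  The
// tail is summed directly over i = f..min(G, s) from the smallest log-term
// upward with Kahan compensation, so scores (-log10 p) up to several
// hundred stay finite and accurate.

static double log_choose(double n, double k) {
  if (k < 0.0 || k > n) return R_NegInf;   // C(n, k) = 0 outside support
  return std::lgamma(n + 1.0) - std::lgamma(k + 1.0) - std::lgamma(n - k + 1.0);
}

// [[Rcpp::export]]
Rcpp::NumericVector hyper_tail_log(Rcpp::IntegerVector N,
                                   Rcpp::IntegerVector G,
                                   Rcpp::IntegerVector s,
                                   Rcpp::IntegerVector f) {
  R_xlen_t n = N.size();
  Rcpp::NumericVector out(n);
  for (R_xlen_t r = 0; r < n; ++r) {
    double Nn = N[r], Gg = G[r], ss = s[r], ff = f[r];
    int hi = (int)std::min(Gg, ss);
    if (ff <= 0) { out[r] = 0.0; continue; }          // P(X >= 0) = 1
    if (ff > hi) { out[r] = R_NegInf; continue; }
    double denom = log_choose(Nn, ss);
    int nterm = hi - (int)ff + 1;
    std::vector<double> lt(nterm);
    double lmax = R_NegInf;
    for (int i = (int)ff; i <= hi; ++i) {
      double v = log_choose(Gg, i) + log_choose(Nn - Gg, ss - i) - denom;
      lt[i - (int)ff] = v;
      if (v > lmax) lmax = v;
    }
    // sum exp(lt - lmax) from the smallest term upward, Kahan-compensated
    std::sort(lt.begin(), lt.end());
    double sum = 0.0, comp = 0.0;
    for (int i = 0; i < nterm; ++i) {
      double y = std::exp(lt[i] - lmax) - comp;
      double t = sum + y;
      comp = (t - sum) - y;
      sum = t;
    }
    out[r] = lmax + std::log(sum);
    if (out[r] > 0.0) out[r] = 0.0;                   // numerical guard
  }
  return out;
}
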