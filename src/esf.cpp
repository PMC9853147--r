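#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// log-sum-exp of two log-scale values, tolerant of -Inf
static inline double lse(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// Log elementary symmetric functions gamma_0 .. gamma_k of eps_j = exp(logeps_j).
// Computed entirely in log space so difficulties spanning the full D-score
// range (tens of logits) cannot overflow.
// [[Rcpp::export]]
NumericVector esf_log(NumericVector logeps) {
  int k = logeps.size();
  NumericVector lg(k + 1, R_NegInf);
  lg[0] = 0.0;
  for (int j = 0; j < k; ++j) {
    int top = std::min(j + 1, k);
    for (int r = top; r >= 1; --r) {
      lg[r] = lse(lg[r], logeps[j] + lg[r - 1]);
    }
  }
  return lg;
}

// Conditional pass probabilities pi_{j,r} = P(X_j = 1 | raw score r) for the
// dichotomous Rasch model: pi_{j,r} = eps_j * gamma^{(-j)}_{r-1} / gamma_r,
// where gamma^{(-j)} are the ESFs excluding item j.  The exclusion ESFs are
// recomputed by a fresh log-space DP per item (O(k^3) total) rather than the
// classical subtraction recursion, which cancels catastrophically for widely
// spread difficulties.
// Returns a list with lg (log ESF, length k+1) and pi (k x (k-1), columns r=1..k-1).
// [[Rcpp::export]]
List cml_pi(NumericVector logeps) {
  int k = logeps.size();
  NumericVector lg = esf_log(logeps);
  NumericMatrix pi(k, k - 1);
  std::vector<double> lgj(k, R_NegInf);
  for (int j = 0; j < k; ++j) {
    std::fill(lgj.begin(), lgj.end(), R_NegInf);
    lgj[0] = 0.0;
    int deg = 0;
    for (int i = 0; i < k; ++i) {
      if (i == j) continue;
      ++deg;
      int top = std::min(deg, k - 1);
      for (int r = top; r >= 1; --r) {
        lgj[r] = lse(lgj[r], logeps[i] + lgj[r - 1]);
      }
    }
    for (int r = 1; r <= k - 1; ++r) {
      pi(j, r - 1) = std::exp(logeps[j] + lgj[r - 1] - lg[r]);
    }
  }
  return List::create(Named("lg") = lg, Named("pi") = pi);
}
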