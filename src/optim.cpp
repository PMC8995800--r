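#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fused in-place optimizer updates.  The training loop owns its parameter
// and state buffers (they are duplicated once when training starts), so
// updating them in place is safe and avoids reallocating large arrays on
// every step.

// [[Rcpp::export]]
void adam_step_inplace(NumericVector p, NumericVector m, NumericVector v,
                       NumericVector g, double lr, double beta1,
                       double beta2, double eps, int t) {
  const double c1 = 1.0 - std::pow(beta1, (double)t);
  const double c2s = std::sqrt(1.0 - std::pow(beta2, (double)t));
  // fold the bias corrections into the step size (lr' * m / (sqrt(v) + eps'))
  const double lrt = lr * c2s / c1;
  const double epst = eps * c2s;
  const double om1 = 1.0 - beta1, om2 = 1.0 - beta2;
  const R_xlen_t n = p.size();
  double *pp = p.begin(), *pm = m.begin(), *pv = v.begin(), *pg = g.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = pg[i];
    const double mi = beta1 * pm[i] + om1 * gi;
    const double vi = beta2 * pv[i] + om2 * gi * gi;
    pm[i] = mi;
    pv[i] = vi;
    pp[i] -= lrt * mi / (std::sqrt(vi) + epst);
  }
}

// [[Rcpp::export]]
void rmsprop_step_inplace(NumericVector p, NumericVector a, NumericVector g,
                          double lr, double rho, double eps) {
  const R_xlen_t n = p.size();
  const double om = 1.0 - rho;
  double *pp = p.begin(), *pa = a.begin(), *pg = g.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = pg[i];
    const double ai = rho * pa[i] + om * gi * gi;
    pa[i] = ai;
    pp[i] -= lr * gi / (std::sqrt(ai) + eps);
  }
}
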