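// In-place Adam update over flat parameter/state lists. The R caller owns
// private copies of the lists (created once per training run), so updating
// the numeric vectors in place is safe and avoids reallocating ~10^6
// doubles per step.

#include <Rcpp.h>
using namespace Rcpp;

// gscale rescales every gradient before the update (global-norm clipping
// is computed by the caller).
// [[Rcpp::export]]
void cn_adam_update(List params, List grads, List m, List v, int t,
                    double lr, double beta1, double beta2, double eps,
                    double gscale = 1.0) {
  int n = params.size();
  double bc1 = 1.0 - std::pow(beta1, (double)t);
  double bc2 = 1.0 - std::pow(beta2, (double)t);
  CharacterVector names = params.names();
  for (int i = 0; i < n; ++i) {
    NumericVector p = params[i];
    std::string nm = as<std::string>(names[i]);
    NumericVector g = grads[nm];
    NumericVector mi = m[i];
    NumericVector vi = v[i];
    R_xlen_t len = p.size();
    if (g.size() != len || mi.size() != len || vi.size() != len) {
      stop("adam state size mismatch for '%s'", nm);
    }
    for (R_xlen_t j = 0; j < len; ++j) {
      double gj = g[j] * gscale;
      mi[j] = beta1 * mi[j] + (1.0 - beta1) * gj;
      vi[j] = beta2 * vi[j] + (1.0 - beta2) * gj * gj;
      double mhat = mi[j] / bc1;
      double vhat = vi[j] / bc2;
      p[j] -= lr * mhat / (std::sqrt(vhat) + eps);
    }
  }
}

// Squared global norm of a gradient list.
// [[Rcpp::export]]
double cn_grad_sqnorm(List grads) {
  double s = 0;
  for (int i = 0; i < grads.size(); ++i) {
    NumericVector g = grads[i];
    for (R_xlen_t j = 0; j < g.size(); ++j) s += g[j] * g[j];
  }
  return s;
}
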