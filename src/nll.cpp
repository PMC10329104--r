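#include <Rcpp.h>
using namespace Rcpp;

// Negative log-likelihood of one subject's session under the hybrid
// model-based / model-free agent with stake-conditioned mixture weights.
//
// par: alpha, beta, lam, w_low, w_high, pi, rho
// enc: integer matrix, one row per trial, columns
//   0 ship index of the left option (0..3)
//   1 ship index of the right option
//   2 chosen side (0 = left, 1 = right, -1 = missed)
//   3 destination planet of the left option (0/1)
//   4 destination planet of the right option
//   5 high-stake flag (0/1)
// rsc: received treasure scaled to [0, 1] (NA on missed trials)
//
// Missed trials contribute no likelihood and trigger no value update.
// [[Rcpp::export]]
double nll_cpp(NumericVector par, IntegerMatrix enc, NumericVector rsc) {
  const double alpha = par[0], beta = par[1], lam = par[2];
  const double w_low = par[3], w_high = par[4], pi = par[5], rho = par[6];
  double q[4] = {0.5, 0.5, 0.5, 0.5};
  double v[2] = {0.5, 0.5};
  int prev_planet = -1, prev_key = -1;
  double nll = 0.0;
  const int n = enc.nrow();
  for (int t = 0; t < n; ++t) {
    const int chosen = enc(t, 2);
    if (chosen < 0) continue;
    const int s[2] = {enc(t, 0), enc(t, 1)};
    const int d[2] = {enc(t, 3), enc(t, 4)};
    const double w = enc(t, 5) ? w_high : w_low;
    double logit[2];
    for (int i = 0; i < 2; ++i) {
      const double q_net = w * v[d[i]] + (1.0 - w) * q[s[i]];
      logit[i] = beta * q_net;
      if (prev_planet >= 0 && d[i] == prev_planet) logit[i] += pi;
      if (prev_key >= 0 && i == prev_key) logit[i] += rho;
    }
    const double m = logit[0] > logit[1] ? logit[0] : logit[1];
    const double e0 = std::exp(logit[0] - m), e1 = std::exp(logit[1] - m);
    nll -= (logit[chosen] - m) - std::log(e0 + e1);
    // TD update with eligibility trace
    const int a = s[chosen], dd = d[chosen];
    const double r = rsc[t];
    const double d1 = v[dd] - q[a];
    q[a] += alpha * d1;
    const double d2 = r - v[dd];
    v[dd] += alpha * d2;
    q[a] += alpha * lam * d2;
    prev_planet = dd;
    prev_key = chosen;
  }
  return nll;
}
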