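#include <Rcpp.h>
using namespace Rcpp;

// Trial-by-trial predicted means for the four learning models.
//
// model codes: 1 = RW1, 2 = RW2, 3 = PH1, 4 = PH2.
// params: RW1 {k}; RW2 {k_plus, k_minus}; PH1 {k1, gamma}; PH2 {k1, gamma, nu}.
// One learner state is kept per distribution (dist_index, 1-based): the cue
// identifies the "pot", so predictions are pot-specific. Missed trials leave
// the state untouched (the reward was never shown). The Pearce-Hall rate is
// driven by the absolute PE relative to a 20-GBP reference error (the rate
// saturates for PEs of 20 GBP and above) and clipped to [0, 1]; the log-SD
// scaling coefficient D is fixed at 1. mu is clipped to [0, 100] after
// every update.
// When `anchored` is true and an observed prediction is available, each
// update steps from that observed prediction (the PE the agent actually
// saw: reward minus stated prediction) rather than from the latent mean.
// This is the one-step-ahead conditional form used for fitting; the latent
// form (anchored = false) is the pure forward simulation of the model.
// [[Rcpp::export]]
NumericVector mu_series_cpp(int model, NumericVector params,
                            NumericVector rewards, NumericVector sds,
                            IntegerVector dist_index, LogicalVector missed,
                            NumericVector mu_init, bool anchored,
                            NumericVector predictions) {
  int n = rewards.size();
  int ndist = mu_init.size();
  NumericVector mu_out(n);
  std::vector<double> mu(ndist), krate(ndist);
  for (int d = 0; d < ndist; ++d) {
    mu[d] = mu_init[d];
    if (model >= 3) krate[d] = params[0];
  }
  for (int t = 0; t < n; ++t) {
    int d = dist_index[t] - 1;
    mu_out[t] = mu[d];
    if (missed[t]) continue;
    if (anchored && !NumericVector::is_na(predictions[t]))
      mu[d] = predictions[t];
    double delta = rewards[t] - mu[d];
    double upd = 0.0;
    if (model == 1) {
      upd = params[0] * delta;
    } else if (model == 2) {
      upd = (delta >= 0 ? params[0] : params[1]) * delta;
    } else {
      double gamma = params[1];
      double k = (1.0 - gamma) * krate[d] + gamma * (std::fabs(delta) / 20.0);
      if (k > 1.0) k = 1.0;
      krate[d] = k;
      double eff = delta;
      if (model == 4) {
        double nu = params[2];
        if (nu > 0.0) eff = delta / std::pow(std::log(sds[t]), nu);
      }
      upd = k * eff;
    }
    mu[d] += upd;
    if (mu[d] < 0.0) mu[d] = 0.0;
    if (mu[d] > 100.0) mu[d] = 100.0;
  }
  return mu_out;
}
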