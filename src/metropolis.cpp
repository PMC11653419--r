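#include <Rcpp.h>
using namespace Rcpp;

// log posterior of a two-parameter logistic regression
// y_i ~ Bernoulli(plogis(t1 + t2 * x_i)) with independent zero-centered
// normal priors on (t1, t2); overflow-safe log1p(exp(.)) evaluation
static double log_post(const NumericVector &x, const NumericVector &y,
                       double t1, double t2,
                       double prior_sd1, double prior_sd2) {
  double ll = 0.0;
  const int n = x.size();
  for (int i = 0; i < n; ++i) {
    double eta = t1 + t2 * x[i];
    double lse = (eta > 35.0) ? eta : log1p(exp(eta));
    ll += y[i] * eta - lse;
  }
  ll += -0.5 * (t1 / prior_sd1) * (t1 / prior_sd1);
  ll += -0.5 * (t2 / prior_sd2) * (t2 / prior_sd2);
  return ll;
}

// Adaptive random-walk Metropolis for the 2-parameter logistic posterior.
// The proposal is a bivariate normal with (lower) Cholesky factor
// `chol_prop` scaled by an adaptive factor tuned toward `target_accept`
// during burn-in (Robbins-Monro on the log scale) and frozen afterwards.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List rw_metropolis_logistic(NumericVector x, NumericVector y,
                            NumericVector init, NumericMatrix chol_prop,
                            double prior_sd1, double prior_sd2,
                            int n_draws, int n_burn,
                            double target_accept) {
  RNGScope scope;
  NumericMatrix draws(n_draws, 2);
  double t1 = init[0], t2 = init[1];
  double lp = log_post(x, y, t1, t2, prior_sd1, prior_sd2);
  double log_scale = 0.0;
  int accepted_post = 0;
  const int total = n_burn + n_draws;
  for (int iter = 0; iter < total; ++iter) {
    double z1 = R::norm_rand();
    double z2 = R::norm_rand();
    double sc = exp(log_scale);
    double p1 = t1 + sc * chol_prop(0, 0) * z1;
    double p2 = t2 + sc * (chol_prop(1, 0) * z1 + chol_prop(1, 1) * z2);
    double lp_prop = log_post(x, y, p1, p2, prior_sd1, prior_sd2);
    bool accept = log(R::unif_rand()) < lp_prop - lp;
    if (accept) {
      t1 = p1; t2 = p2; lp = lp_prop;
    }
    if (iter < n_burn) {
      double gain = 1.0 / sqrt((double)(iter + 1));
      log_scale += gain * ((accept ? 1.0 : 0.0) - target_accept);
    } else {
      if (accept) ++accepted_post;
      draws(iter - n_burn, 0) = t1;
      draws(iter - n_burn, 1) = t2;
    }
  }
  return List::create(
    _["draws"] = draws,
    _["accept_rate"] = (double)accepted_post / (double)n_draws,
    _["scale"] = exp(log_scale));
}
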