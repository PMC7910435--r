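#include <Rcpp.h>
using namespace Rcpp;

// Variant codes shared with R/variants.R:
// 0 rbar_full, 1 null_no_learning, 2 no_effort_cost,
// 3 fixed_effort_cost, 4 increasing_effort_cost, 5 pavlovian_only

static inline double clamp_exp(double x, double lim, int *nclamp) {
  if (x > lim) { (*nclamp)++; return lim; }
  if (x < -lim) { (*nclamp)++; return -lim; }
  return x;
}

static inline double effort_cost(int variant, double C, double tau) {
  switch (variant) {
  case 2: return 0.0;            // no effort cost term
  case 3: return C;              // fixed cost per response
  case 4: return C * tau;        // cost increasing with latency
  default: return C / tau;       // amortized over the latency
  }
}

// Forward pass over observed latencies. Returns per-interval policy, rbar,
// delta, mu and the accumulated negative log-likelihood of tau | mu under
// an exponential with mean mu. Policy updates need a latency difference, so
// they begin at the second interval; rbar updates begin at the first.
// [[Rcpp::export(name = ".rrl_forward_cpp")]]
List rrl_forward_cpp(NumericVector tau, NumericVector reward,
                     double alpha, double P, double C,
                     int variant, double rbar0, double exp_clamp) {
  int m = tau.size();
  NumericVector policy(m), rbar(m), delta(m), mu(m);
  int nclamp = 0;
  double pol = P, rb = rbar0, nll = 0.0;
  for (int j = 0; j < m; ++j) {
    policy[j] = pol;
    rbar[j] = rb;
    double expo;
    if (variant == 1) {
      expo = P;                       // stable tendency, no learning
    } else if (variant == 5) {
      expo = P - alpha * rb;          // frozen policy, Pavlovian term only
    } else {
      expo = pol - alpha * rb;
    }
    expo = clamp_exp(expo, exp_clamp, &nclamp);
    double m_j = std::exp(expo);
    mu[j] = m_j;
    nll += std::log(m_j) + tau[j] / m_j;
    double d = reward[j] - effort_cost(variant, C, tau[j]) - rb * tau[j];
    delta[j] = d;
    if (variant != 1) {
      if (j >= 1 && variant != 5)
        pol += alpha * (tau[j] - tau[j - 1]) * d;
      rb += alpha * d;
    }
  }
  return List::create(_["policy"] = policy, _["rbar"] = rbar,
                      _["delta"] = delta, _["mu"] = mu,
                      _["nll"] = nll, _["nclamp"] = nclamp);
}

// Likelihood-only version of the forward pass (hot path for fitting).
// [[Rcpp::export(name = ".rrl_nll_cpp")]]
double rrl_nll_cpp(NumericVector tau, NumericVector reward,
                   double alpha, double P, double C,
                   int variant, double rbar0, double exp_clamp) {
  int m = tau.size(), nclamp = 0;
  double pol = P, rb = rbar0, nll = 0.0;
  for (int j = 0; j < m; ++j) {
    double expo;
    if (variant == 1) expo = P;
    else if (variant == 5) expo = P - alpha * rb;
    else expo = pol - alpha * rb;
    expo = clamp_exp(expo, exp_clamp, &nclamp);
    double m_j = std::exp(expo);
    nll += std::log(m_j) + tau[j] / m_j;
    double d = reward[j] - effort_cost(variant, C, tau[j]) - rb * tau[j];
    if (variant != 1) {
      if (j >= 1 && variant != 5)
        pol += alpha * (tau[j] - tau[j - 1]) * d;
      rb += alpha * d;
    }
  }
  return nll;
}

// Simulate an agent against a constant-rate Poisson like process using R's
// RNG (reproducible under set.seed). Custom reward processes use the R-level
// simulator instead.
// [[Rcpp::export(name = ".rrl_simulate_poisson_cpp")]]
List rrl_simulate_poisson_cpp(int n, double lambda,
                              double alpha, double P, double C,
                              int variant, double rbar0, double exp_clamp,
                              double min_latency) {
  NumericVector tau(n), reward(n), policy(n), rbar(n), delta(n), mu(n);
  int nclamp = 0;
  double pol = P, rb = rbar0;
  RNGScope scope;
  for (int j = 0; j < n; ++j) {
    policy[j] = pol;
    rbar[j] = rb;
    double expo;
    if (variant == 1) expo = P;
    else if (variant == 5) expo = P - alpha * rb;
    else expo = pol - alpha * rb;
    expo = clamp_exp(expo, exp_clamp, &nclamp);
    double m_j = std::exp(expo);
    mu[j] = m_j;
    double t_j = R::rexp(m_j);
    // responses take a minimum time to produce; this also bounds the
    // effort-cost spike C / tau, whose expectation diverges otherwise
    if (t_j < min_latency) t_j = min_latency;
    tau[j] = t_j;
    double r_j = R::rpois(lambda);
    reward[j] = r_j;
    double d = r_j - effort_cost(variant, C, t_j) - rb * t_j;
    delta[j] = d;
    if (variant != 1) {
      if (j >= 1 && variant != 5)
        pol += alpha * (tau[j] - tau[j - 1]) * d;
      rb += alpha * d;
    }
  }
  return List::create(_["tau"] = tau, _["reward"] = reward,
                      _["policy"] = policy, _["rbar"] = rbar,
                      _["delta"] = delta, _["mu"] = mu,
                      _["nclamp"] = nclamp);
}
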