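#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Stochastic two-state (active/refractory) Markov population model, two
// populations sharing one set of transition rates. Per step and population:
//   dA_minus ~ Binomial(A, (beta+gamma)*dt)     leave the active pool
//   S        ~ Binomial(dA_minus, gamma/(gamma+beta))   of which spiked
//   dA_plus  ~ Binomial(N - A, alpha*dt)        re-enter the active pool
// with alpha = exp(c0 + c1*S_e + c2*S_i) evaluated at the spike counts of
// the current step (those just drawn), shared by both populations;
// alpha*dt is clipped to [0, 1]. Evaluating alpha after the spike draws is
// what closes the one-step feedback loop of the mean-field equations: the
// inflow during a bin is modulated by the counts of that same bin.
//
// Draw order (exc dA-, exc S, inh dA-, inh S, then both inflows) matches the
// single-step R reference so that both produce identical streams under the
// same RNG seed.
// [[Rcpp::export]]
List arm_simulate_cpp(double c0, double c1, double c2, double beta,
                      double gamma, double dt, int n_exc, int n_inh,
                      long n_steps, int a_e0, int a_i0, int s_e0, int s_i0) {
  const double p_out = (beta + gamma) * dt;
  const double p_spk = gamma / (gamma + beta);
  if (p_out < 0.0 || p_out > 1.0) stop("(beta+gamma)*dt must lie in [0,1]");

  IntegerVector S_e(n_steps), S_i(n_steps), A_e(n_steps), A_i(n_steps);
  int ae = a_e0, ai = a_i0, se = s_e0, si = s_i0;
  RNGScope scope;

  for (long t = 0; t < n_steps; ++t) {
    int dme = (int)::Rf_rbinom(ae, p_out);
    int se_new = (int)::Rf_rbinom(dme, p_spk);
    int dmi = (int)::Rf_rbinom(ai, p_out);
    int si_new = (int)::Rf_rbinom(dmi, p_spk);

    double alpha = std::exp(c0 + c1 * se_new + c2 * si_new);
    double p_in = alpha * dt;
    if (p_in > 1.0) p_in = 1.0;
    int dpe = (int)::Rf_rbinom(n_exc - ae, p_in);
    int dpi = (int)::Rf_rbinom(n_inh - ai, p_in);

    ae += dpe - dme;
    ai += dpi - dmi;
    se = se_new;
    si = si_new;
    S_e[t] = se; S_i[t] = si; A_e[t] = ae; A_i[t] = ai;
    if ((t & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["S_e"] = S_e, _["S_i"] = S_i,
                      _["A_e"] = A_e, _["A_i"] = A_i);
}
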