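#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Inversion sampler for small-mean Poisson; table covers essentially all mass,
// tail falls back to R's rpois. Uses R's RNG stream (caller holds RNG state).
struct PoisTable {
  std::vector<double> cdf;
  double lambda;
  explicit PoisTable(double lam) : lambda(lam) {
    double p = std::exp(-lam), c = p;
    cdf.push_back(c);
    int k = 0;
    while (c < 1.0 - 1e-13 && k < 64) {
      ++k;
      p *= lam / k;
      c += p;
      cdf.push_back(c);
    }
  }
  inline int draw() {
    double u = unif_rand();
    for (size_t k = 0; k < cdf.size(); ++k)
      if (u <= cdf[k]) return (int)k;
    return (int)::Rf_rpois(lambda);
  }
};

// Simulate a network of LIF neurons with delta-pulse synapses on a fixed time
// grid. Between grid points the membrane decays exactly (factor exp(-dt/tau));
// all synaptic and external events arriving within a step are accumulated and
// applied at the step boundary. Spikes emitted at step t are delivered after
// delay_steps. During refractoriness the potential is clamped at v_reset and
// incoming events are discarded.
//
// exc_sources / inh_sources: in-edge matrices (k_exc x N resp. k_inh x N),
// 1-based neuron indices; column i lists the presynaptic sources of neuron i.
// [[Rcpp::export]]
List lif_simulate_cpp(int n_exc, int n_inh,
                      IntegerMatrix exc_sources, IntegerMatrix inh_sources,
                      double j_psp, double g, double tau_m, double theta,
                      double v_reset, double t_ref, double t_delay,
                      double nu_ext, double dt, double duration,
                      NumericVector v0, IntegerVector record_v_ids) {
  const int n_tot = n_exc + n_inh;
  const long n_steps = (long)std::lround(duration / dt);
  const int delay_steps = std::max(1, (int)std::lround(t_delay / dt));
  const int refr_steps = (int)std::lround(t_ref / dt);
  const double decay = std::exp(-dt / tau_m);
  const double lam_ext = nu_ext * dt;
  const double w_exc = j_psp, w_inh = -g * j_psp;

  // forward adjacency in CSR layout, built from the in-edge lists:
  // offs[s]..offs[s+1] delimits the targets of 0-based source s
  std::vector<long> offs(n_tot + 1, 0);
  {
    for (int i = 0; i < n_tot; ++i) {
      for (int r = 0; r < exc_sources.nrow(); ++r) offs[exc_sources(r, i)]++;
      for (int r = 0; r < inh_sources.nrow(); ++r) offs[inh_sources(r, i)]++;
    }
    for (int s = 1; s <= n_tot; ++s) offs[s] += offs[s - 1];
  }
  std::vector<int> targets(offs[n_tot]);
  {
    std::vector<long> pos(offs.begin(), offs.end() - 1);
    for (int i = 0; i < n_tot; ++i) {
      for (int r = 0; r < exc_sources.nrow(); ++r)
        targets[pos[exc_sources(r, i) - 1]++] = i;
      for (int r = 0; r < inh_sources.nrow(); ++r)
        targets[pos[inh_sources(r, i) - 1]++] = i;
    }
  }

  std::vector<double> v(n_tot);
  for (int i = 0; i < n_tot; ++i) v[i] = (v0.size() == n_tot) ? v0[i] : 0.0;
  std::vector<long> ref_until(n_tot, -1);
  // ring buffer of pending synaptic input, one slot per delay step
  std::vector< std::vector<double> > pending(delay_steps,
                                             std::vector<double>(n_tot, 0.0));

  std::vector<int> spk_id;
  std::vector<double> spk_t;
  spk_id.reserve(1 << 20);
  spk_t.reserve(1 << 20);
  std::vector<int> step_spikes;
  step_spikes.reserve(1024);

  const int n_rec = record_v_ids.size();
  NumericMatrix v_trace(n_rec > 0 ? n_steps : 0, n_rec);

  PoisTable pois(lam_ext);
  const bool has_ext = lam_ext > 0.0;
  RNGScope scope;

  for (long t = 0; t < n_steps; ++t) {
    std::vector<double>& inbox = pending[t % delay_steps];
    step_spikes.clear();
    for (int i = 0; i < n_tot; ++i) {
      if (t < ref_until[i]) {
        v[i] = v_reset;  // clamped; arriving events discarded
      } else {
        double vi = v[i] * decay + inbox[i];
        if (has_ext) {
          int k = pois.draw();
          if (k) vi += w_exc * k;
        }
        if (vi >= theta) {
          step_spikes.push_back(i);
          vi = v_reset;
          ref_until[i] = t + refr_steps;
        }
        v[i] = vi;
      }
      inbox[i] = 0.0;
    }
    if (n_rec > 0)
      for (int r = 0; r < n_rec; ++r) v_trace(t, r) = v[record_v_ids[r] - 1];
    if (!step_spikes.empty()) {
      // deliver at step t + delay_steps, i.e. back into the slot just cleared
      std::vector<double>& outbox = pending[t % delay_steps];
      double tms = t * dt;
      for (size_t s = 0; s < step_spikes.size(); ++s) {
        int j = step_spikes[s];
        spk_id.push_back(j + 1);
        spk_t.push_back(tms);
        double w = (j < n_exc) ? w_exc : w_inh;
        for (long e = offs[j]; e < offs[j + 1]; ++e) outbox[targets[e]] += w;
      }
    }
    if ((t & 0xFFFF) == 0) {
      for (int i = 0; i < n_tot; ++i)
        if (!std::isfinite(v[i]))
          stop("non-finite membrane potential at t = %f ms", t * dt);
      Rcpp::checkUserInterrupt();
    }
  }

  return List::create(_["neuron"] = wrap(spk_id),
                      _["time_ms"] = wrap(spk_t),
                      _["v_trace"] = v_trace,
                      _["v_final"] = wrap(v));
}
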