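#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Discrete-event (Gillespie) simulation of the spiking random neural
// network. State: nonnegative integer potentials k[l]. Competing
// exponential clocks: external excitatory arrivals (rate lp[l]), external
// inhibitory arrivals (rate lm[l]), and firing of excited neurons (rate
// r[l] while k[l] > 0). A fired spike routes to neuron j as excitatory
// with probability w_plus[l][j]/r[l], inhibitory with w_minus[l][j]/r[l],
// and leaves the network otherwise. Busy fractions are time averages of
// 1{k[l] > 0}; a burn-in prefix is discarded and the remainder is split
// into batches whose means give a standard error that honours the
// autocorrelation of the process.
// [[Rcpp::export]]
List simulate_network_cpp(NumericMatrix w_plus, NumericMatrix w_minus,
                          NumericVector r, NumericVector lambda_plus,
                          NumericVector lambda_minus, double n_events,
                          int seed, int n_batches = 100,
                          double burn_in = 0.1) {
  const int N = r.size();
  std::mt19937_64 rng(static_cast<unsigned long long>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<long long> k(N, 0);
  std::vector<double> busy(N, 0.0);
  std::vector<double> batch_busy((size_t)n_batches * N, 0.0);
  std::vector<double> batch_time(n_batches, 0.0);

  const double ext_rate_p = sum(lambda_plus);
  const double ext_rate_m = sum(lambda_minus);
  long long burn_events = (long long)(burn_in * n_events);
  long long measured_events = (long long)n_events - burn_events;
  if (measured_events < 1) { burn_events = 0; measured_events = (long long)n_events; }
  long long per_batch = measured_events / n_batches;
  if (per_batch < 1) { per_batch = measured_events; n_batches = 1; }

  double total_time = 0.0;
  long long ev = 0;
  for (; ev < (long long)n_events; ++ev) {
    double fire_rate = 0.0;
    for (int l = 0; l < N; ++l) if (k[l] > 0) fire_rate += r[l];
    double total_rate = ext_rate_p + ext_rate_m + fire_rate;
    if (total_rate <= 0.0) break;  // absorbed: no event can occur

    double dt = -std::log(1.0 - unif(rng)) / total_rate;
    if (ev >= burn_events) {
      int b = (int)std::min<long long>((ev - burn_events) / per_batch,
                                       n_batches - 1);
      batch_time[b] += dt;
      total_time += dt;
      for (int l = 0; l < N; ++l) if (k[l] > 0) {
        busy[l] += dt;
        batch_busy[(size_t)b * N + l] += dt;
      }
    }

    double u = unif(rng) * total_rate;
    if (u < ext_rate_p) {                       // external excitatory
      for (int l = 0; l < N; ++l) {
        u -= lambda_plus[l];
        if (u < 0) { ++k[l]; break; }
      }
    } else if (u < ext_rate_p + ext_rate_m) {   // external inhibitory
      u -= ext_rate_p;
      for (int l = 0; l < N; ++l) {
        u -= lambda_minus[l];
        if (u < 0) { if (k[l] > 0) --k[l]; break; }
      }
    } else {                                    // firing
      u -= ext_rate_p + ext_rate_m;
      int src = -1;
      for (int l = 0; l < N; ++l) if (k[l] > 0) {
        u -= r[l];
        if (u < 0) { src = l; break; }
      }
      if (src < 0) src = N - 1;  // numerical edge
      --k[src];
      double v = unif(rng) * r[src];
      bool routed = false;
      for (int j = 0; j < N && !routed; ++j) {
        v -= w_plus(src, j);
        if (v < 0) { ++k[j]; routed = true; }
      }
      if (!routed) for (int j = 0; j < N && !routed; ++j) {
        v -= w_minus(src, j);
        if (v < 0) { if (k[j] > 0) --k[j]; routed = true; }
      }
      // otherwise the spike departs the network (probability d)
    }
  }

  NumericVector frac(N), se(N);
  if (total_time > 0) {
    for (int l = 0; l < N; ++l) frac[l] = busy[l] / total_time;
    // standard error from batch means (batches weighted equally)
    for (int l = 0; l < N; ++l) {
      double m = 0.0; int nb = 0;
      std::vector<double> bm;
      for (int b = 0; b < n_batches; ++b) if (batch_time[b] > 0) {
        bm.push_back(batch_busy[(size_t)b * N + l] / batch_time[b]);
        m += bm.back(); ++nb;
      }
      if (nb > 1) {
        m /= nb;
        double s2 = 0.0;
        for (double x : bm) s2 += (x - m) * (x - m);
        se[l] = std::sqrt(s2 / (nb - 1) / nb);
      } else se[l] = NA_REAL;
    }
  }
  return List::create(_["busy_fraction"] = frac, _["se"] = se,
                      _["total_time"] = total_time,
                      _["events"] = (double)ev);
}
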