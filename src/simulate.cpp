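#include <Rcpp.h>
using namespace Rcpp;

// One host's trajectory of the within-host death-birth-immigration process
// with host resetting. Counts are (n0, n1, ..., nM) with n0 = empty slots.
//
// Per step the draw order from R's RNG stream is fixed:
//   u1: host death test (u1 < tau -> reset to microbe-free state)
//   u2: slot selection, uniform over the N slots (type chosen prop. to n_j)
//   u3: replacement draw from m * pool + (1 - m) * fitness-weighted local
// No draws are consumed after a reset within the same step.
//
// sample_times must be sorted non-negative step counts (0 = initial state);
// the returned integer matrix has one row per sample time, one column per
// type.
// [[Rcpp::export]]
IntegerMatrix sim_host_counts(IntegerVector n_init,
                              int n_steps,
                              IntegerVector sample_times,
                              double m,
                              double tau,
                              NumericVector pool,
                              NumericVector alpha) {
  const int K = n_init.size();          // M + 1 types including empty space
  if (pool.size() != K || alpha.size() != K)
    stop("pool and alpha must have length M + 1");
  long N = 0;
  std::vector<long> n(K);
  for (int j = 0; j < K; ++j) { n[j] = n_init[j]; N += n[j]; }

  const int S = sample_times.size();
  IntegerMatrix out(S, K);
  int s = 0;
  std::vector<double> w(K);

  // record any samples scheduled at time 0
  while (s < S && sample_times[s] == 0) {
    for (int j = 0; j < K; ++j) out(s, j) = (int) n[j];
    ++s;
  }

  for (int t = 1; t <= n_steps && s < S; ++t) {
    if (tau > 0.0 && unif_rand() < tau) {
      // host death: newborn host is microbe-free
      n[0] = N;
      for (int j = 1; j < K; ++j) n[j] = 0;
    } else {
      // pick the slot whose content dies: type prop. to n_j
      double u2 = unif_rand() * (double) N;
      int dead = K - 1;
      double acc = 0.0;
      for (int j = 0; j < K; ++j) {
        acc += (double) n[j];
        if (u2 < acc) { dead = j; break; }
      }
      // replacement distribution
      double wsum = 0.0;
      for (int j = 0; j < K; ++j) {
        w[j] = (1.0 + alpha[j]) * (double) n[j];
        wsum += w[j];
      }
      double u3 = unif_rand();
      int born = K - 1;
      acc = 0.0;
      for (int j = 0; j < K; ++j) {
        acc += m * pool[j] + (1.0 - m) * w[j] / wsum;
        if (u3 < acc) { born = j; break; }
      }
      n[dead] -= 1;
      n[born] += 1;
    }
    while (s < S && sample_times[s] == t) {
      for (int j = 0; j < K; ++j) out(s, j) = (int) n[j];
      ++s;
    }
  }
  return out;
}
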