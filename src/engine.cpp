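#include <Rcpp.h>
using namespace Rcpp;

// Coalescent waiting time for k lineages under an instantaneous size change:
// rate k(k-1)/(2M) per generation with M = n_cur for t < tau and
// M = eps * n_cur for t >= tau.  A single unit exponential is rescaled across
// the boundary (valid by memorylessness).
// Unit exponential via inversion of unif_rand(); cheaper than exp_rand() and
// still driven by R's seeded generator.
static inline double exp1(void) {
  double u;
  do { u = unif_rand(); } while (u <= 0.0);
  return -std::log(u);
}

// sc0 = N0/pair, isc0 = pair/N0, sca = Na/pair (pair = k(k-1)/2)
static inline double level_time(double t, double sc0, double isc0, double sca,
                                double tau) {
  double e = exp1();
  if (t < tau) {
    double w1 = e * sc0;
    if (t + w1 <= tau) return w1;
    return (tau - t) + (e - (tau - t) * isc0) * sca;
  }
  return e * sca;
}

// FREQ-mode folded SFS sampler.  Each genealogy contributes exactly one SNP.
// Conditional on the level times T_k, the SNP's derived class is a mixture:
// pick level k with probability k*T_k / sum(k*T_k), then a block size from the
// classical distribution of the number of descendants of a uniformly chosen
// lineage among k ancestors of n samples (independent of times).  cumQ holds
// the cumulative class distribution per level, row (k-2), columns i = 1..n-k+1.
// [[Rcpp::export]]
IntegerMatrix sfs_freq_engine_cpp(int n_samples, int n_genealogies,
                                  NumericVector n_cur, NumericVector eps,
                                  NumericVector tau, NumericMatrix cumQ) {
  int n_demog = n_cur.size();
  int n_fold = n_samples / 2;
  IntegerMatrix out(n_demog, n_fold);
  std::vector<double> w(n_samples + 1, 0.0);
  std::vector<double> sc0(n_samples + 1), isc0(n_samples + 1),
      sca(n_samples + 1);
  for (int d = 0; d < n_demog; ++d) {
    double N0 = n_cur[d];
    double Na = eps[d] * N0;
    double td = tau[d];
    for (int k = 2; k <= n_samples; ++k) {
      double pair = k * (k - 1) / 2.0;
      sc0[k] = N0 / pair;
      isc0[k] = pair / N0;
      sca[k] = Na / pair;
    }
    for (int g = 0; g < n_genealogies; ++g) {
      double t = 0.0, L = 0.0;
      for (int k = n_samples; k >= 2; --k) {
        double dt = level_time(t, sc0[k], isc0[k], sca[k], td);
        t += dt;
        double wk = k * dt;
        w[k] = wk;
        L += wk;
      }
      // level draw; scan from k = 2 where most mass usually sits
      double u = unif_rand() * L, c = 0.0;
      int lev = n_samples;
      for (int k = 2; k <= n_samples; ++k) {
        c += w[k];
        if (u <= c) { lev = k; break; }
      }
      // class draw from the level's block-size distribution
      double v = unif_rand();
      int maxi = n_samples - lev + 1;
      int cls = maxi;
      for (int i = 0; i < maxi; ++i) {
        if (v <= cumQ(lev - 2, i)) { cls = i + 1; break; }
      }
      int f = (cls <= n_samples - cls) ? cls : n_samples - cls;
      out(d, f - 1)++;
    }
  }
  return out;
}

// Monte-Carlo estimate of E[l_i / l_tot] (folded), averaging the conditional
// class distribution sum_k (k T_k / l_tot) q(. | k) over replicate time draws.
// Q is the (non-cumulative) block-size distribution, row (k-2).
// [[Rcpp::export]]
NumericVector expected_sfs_mc_cpp(int n_samples, int n_reps, double n_cur,
                                  double eps, double tau, NumericMatrix Q) {
  int n_fold = n_samples / 2;
  NumericVector acc(n_fold);
  std::vector<double> w(n_samples + 1, 0.0);
  std::vector<double> sc0(n_samples + 1), isc0(n_samples + 1),
      sca(n_samples + 1);
  double Na = eps * n_cur;
  for (int k = 2; k <= n_samples; ++k) {
    double pair = k * (k - 1) / 2.0;
    sc0[k] = n_cur / pair;
    isc0[k] = pair / n_cur;
    sca[k] = Na / pair;
  }
  for (int r = 0; r < n_reps; ++r) {
    double t = 0.0, L = 0.0;
    for (int k = n_samples; k >= 2; --k) {
      double dt = level_time(t, sc0[k], isc0[k], sca[k], tau);
      t += dt;
      w[k] = k * dt;
      L += w[k];
    }
    for (int k = 2; k <= n_samples; ++k) {
      double mix = w[k] / L;
      int maxi = n_samples - k + 1;
      for (int i = 1; i <= maxi; ++i) {
        int f = (i <= n_samples - i) ? i : n_samples - i;
        acc[f - 1] += mix * Q(k - 2, i - 1);
      }
    }
  }
  for (int j = 0; j < n_fold; ++j) acc[j] /= n_reps;
  return acc;
}
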