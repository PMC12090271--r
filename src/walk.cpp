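#include <Rcpp.h>
using namespace Rcpp;

// Biased random walk of n flies along a tube of length L (mm), Euler step dt.
// Drift ramps as kappa * (1 - exp(-t/tau)); diffusion sigma * sqrt(dt) * N(0,1).
// Reflecting boundaries at 0 and L. Pairwise soft-core repulsion: flies closer
// than d_ex push apart with displacement 0.5 * eta * (d_ex - dist) each.
// Uses R's RNG so set.seed() in R governs reproducibility.
// [[Rcpp::export(name = ".walk_core")]]
NumericMatrix walk_core(NumericVector x0, int steps, double dt,
                        double kappa, double tau, double sigma,
                        double L, double d_ex, double eta) {
  int n = x0.size();
  NumericMatrix out(n, steps + 1);
  std::vector<double> x(n), disp(n);
  for (int i = 0; i < n; ++i) { x[i] = x0[i]; out(i, 0) = x0[i]; }
  double sqdt = std::sqrt(dt);

  for (int s = 1; s <= steps; ++s) {
    double t = (s - 1) * dt;
    double drift = kappa * dt;
    if (tau > 0) drift *= (1.0 - std::exp(-t / tau));
    for (int i = 0; i < n; ++i) {
      x[i] += drift + sigma * sqdt * R::norm_rand();
    }
    if (d_ex > 0 && n > 1) {
      std::fill(disp.begin(), disp.end(), 0.0);
      for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
          double dx = x[i] - x[j];
          double dist = std::fabs(dx);
          if (dist < d_ex) {
            // deterministic tie-break for coincident flies: lower index left
            double sgn = (dist > 0) ? (dx > 0 ? 1.0 : -1.0) : -1.0;
            double push = 0.5 * eta * (d_ex - dist);
            disp[i] += sgn * push;
            disp[j] -= sgn * push;
          }
        }
      }
      for (int i = 0; i < n; ++i) x[i] += disp[i];
    }
    for (int i = 0; i < n; ++i) {
      // fold into [0, L] (reflecting); per-step excursions are small so
      // the loop runs at most a couple of times
      double xi = x[i];
      while (xi < 0 || xi > L) {
        if (xi < 0) xi = -xi; else xi = 2.0 * L - xi;
      }
      x[i] = xi;
      out(i, s) = xi;
    }
  }
  return out;
}
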