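// Classic RK4 integrator for the stop-flow oxygen disappearance model
//   dP/dt = -(v0 * P) / (p50 + P) + z * (p0 - P)
// with `m` internal sub-steps per output step. Intermediate stages are
// evaluated on max(P, 0) for the consumption term; states below zero are
// clipped to zero and flagged.

#include <Rcpp.h>
using namespace Rcpp;

static inline double rhs(double p, double v0, double p50, double p0, double z) {
  const double pp = p > 0.0 ? p : 0.0;
  return -(v0 * pp) / (p50 + pp) + z * (p0 - p);
}

// [[Rcpp::export(name = ".rk4_decay")]]
List rk4_decay(double v0, double p50, double p0, double z,
               int n, double dt, int m, double p_init) {
  NumericVector p(n + 1);
  p[0] = p_init;
  bool clipped = false;
  const double h = dt / m;
  double y = p_init;
  for (int i = 1; i <= n; ++i) {
    for (int j = 0; j < m; ++j) {
      const double k1 = rhs(y, v0, p50, p0, z);
      const double k2 = rhs(y + h / 2.0 * k1, v0, p50, p0, z);
      const double k3 = rhs(y + h / 2.0 * k2, v0, p50, p0, z);
      const double k4 = rhs(y + h * k3, v0, p50, p0, z);
      y += h / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
      if (!R_FINITE(y)) {
        return List::create(_["p"] = p, _["diverged_at"] = i,
                            _["clipped"] = clipped);
      }
      if (y < 0.0) {
        y = 0.0;
        clipped = true;
      }
    }
    p[i] = y;
  }
  return List::create(_["p"] = p, _["diverged_at"] = 0,
                      _["clipped"] = clipped);
}
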