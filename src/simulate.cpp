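#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// dG/dxi of the gaussian-plus-linear model surface
static inline double surface_grad(double x, const double* amp,
                                  const double* cen, const double* wid,
                                  int ng, double slope) {
  double g = slope;
  for (int j = 0; j < ng; ++j) {
    double z = (x - cen[j]) / wid[j];
    g += -amp[j] * z / wid[j] * std::exp(-0.5 * z * z);
  }
  return g;
}

// Overdamped (Brownian) Euler-Maruyama integration of
//   dxi = -(1/gamma) * d(G + w)/dxi * dt + sqrt(2 kT dt / gamma) * N(0,1)
// with reflecting boundaries at [dom_lo, dom_hi]. Uses R's RNG, so results
// are governed by set.seed() on the R side.
// [[Rcpp::export]]
List simulate_langevin_cpp(double x0, int n_samples, int steps_per_sample,
                           double n_equil_steps, double dt, double gamma,
                           double kT, double center, double k, double pref,
                           NumericMatrix gaussians, double slope,
                           double dom_lo, double dom_hi) {
  NumericVector out(n_samples);
  int ng = gaussians.nrow();
  std::vector<double> amp(ng), cen(ng), wid(ng);
  for (int j = 0; j < ng; ++j) {
    amp[j] = gaussians(j, 0);
    cen[j] = gaussians(j, 1);
    wid[j] = gaussians(j, 2);
  }
  const double noise = std::sqrt(2.0 * kT * dt / gamma);
  const double bias_k2 = 2.0 * pref * k;  // d/dx of pref*k*(x-c)^2
  double x = x0;
  long long n_reflect = 0;
  long long equil = (long long)n_equil_steps;
  long long total = equil + (long long)n_samples * steps_per_sample;
  int isamp = 0;
  for (long long step = 1; step <= total; ++step) {
    double g = surface_grad(x, amp.data(), cen.data(), wid.data(), ng, slope) +
               bias_k2 * (x - center);
    x += -(g / gamma) * dt + noise * norm_rand();
    if (x < dom_lo) { x = 2.0 * dom_lo - x; ++n_reflect; }
    else if (x > dom_hi) { x = 2.0 * dom_hi - x; ++n_reflect; }
    if (step > equil && (step - equil) % steps_per_sample == 0) {
      out[isamp++] = x;
    }
  }
  return List::create(_["samples"] = out,
                      _["n_reflections"] = (double)n_reflect,
                      _["final_x"] = x,
                      _["n_steps"] = (double)total);
}
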