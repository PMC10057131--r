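#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Self-consistent WHAM iteration.
//   P(b)  = sum_i n_i(b) / sum_i N_i exp((f_i - W_i(b)) / kT)
//   f_i   = -kT log sum_b P(b) exp(-W_i(b) / kT)
// iterated until max |delta f_i| < tol (f gauge-fixed by f[0] = 0). Bins
// with zero total counts are excluded from both sums. On an oscillation
// (sign flip of a window's update) that window's step is halved; the step
// factor relaxes back toward 1 otherwise. Returns unnormalized bin weights
// P (arbitrary overall scale; callers anchor the PMF).
// [[Rcpp::export]]
List wham_solve_cpp(NumericMatrix counts, NumericVector Ntot,
                    NumericMatrix bias, double kT, double tol,
                    int max_iter, NumericVector f_init) {
  const int nw = counts.nrow();
  const int nb = counts.ncol();
  std::vector<double> B((size_t)nw * nb);   // exp(-W_i(b)/kT)
  std::vector<double> Cb(nb, 0.0);
  for (int i = 0; i < nw; ++i)
    for (int b = 0; b < nb; ++b) {
      B[(size_t)i * nb + b] = std::exp(-bias(i, b) / kT);
      Cb[b] += counts(i, b);
    }
  std::vector<int> active;
  active.reserve(nb);
  for (int b = 0; b < nb; ++b) if (Cb[b] > 0.0) active.push_back(b);

  std::vector<double> f(nw), fnew(nw), z(nw), P(nb, 0.0);
  std::vector<double> prev_step(nw, 0.0), lambda(nw, 1.0);
  for (int i = 0; i < nw; ++i) f[i] = f_init[i] - f_init[0];

  double delta = R_PosInf;
  int iter = 0;
  bool converged = false;
  while (iter < max_iter) {
    ++iter;
    double fmax = f[0];
    for (int i = 1; i < nw; ++i) if (f[i] > fmax) fmax = f[i];
    for (int i = 0; i < nw; ++i) z[i] = Ntot[i] * std::exp((f[i] - fmax) / kT);
    for (size_t a = 0; a < active.size(); ++a) {
      int b = active[a];
      double denom = 0.0;
      for (int i = 0; i < nw; ++i) denom += z[i] * B[(size_t)i * nb + b];
      P[b] = Cb[b] / denom;  // scale e^{fmax/kT} folded in; gauge-irrelevant
    }
    for (int i = 0; i < nw; ++i) {
      double s = 0.0;
      const double* Bi = &B[(size_t)i * nb];
      for (size_t a = 0; a < active.size(); ++a) s += P[active[a]] * Bi[active[a]];
      fnew[i] = -kT * std::log(s);
    }
    double f0 = fnew[0];
    delta = 0.0;
    for (int i = 0; i < nw; ++i) {
      double step = (fnew[i] - f0) - f[i];
      if (std::fabs(step) > delta) delta = std::fabs(step);
      if (step * prev_step[i] < 0.0) lambda[i] *= 0.5;
      else if (lambda[i] < 1.0) lambda[i] = std::min(1.0, lambda[i] * 1.1);
      prev_step[i] = step;
      f[i] += lambda[i] * step;
    }
    if (delta < tol) { converged = true; break; }
  }

  // recompute bin weights from the final window free energies
  {
    double fmax = f[0];
    for (int i = 1; i < nw; ++i) if (f[i] > fmax) fmax = f[i];
    for (int i = 0; i < nw; ++i) z[i] = Ntot[i] * std::exp((f[i] - fmax) / kT);
    for (size_t a = 0; a < active.size(); ++a) {
      int b = active[a];
      double denom = 0.0;
      for (int i = 0; i < nw; ++i) denom += z[i] * B[(size_t)i * nb + b];
      P[b] = Cb[b] / denom;
    }
  }

  NumericVector f_out(nw), P_out(nb);
  for (int i = 0; i < nw; ++i) f_out[i] = f[i];
  double psum = 0.0;
  for (int b = 0; b < nb; ++b) psum += P[b];
  for (int b = 0; b < nb; ++b) P_out[b] = (Cb[b] > 0.0) ? P[b] / psum : NA_REAL;
  return List::create(_["f"] = f_out, _["p"] = P_out,
                      _["iterations"] = iter, _["converged"] = converged,
                      _["max_delta"] = delta);
}
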