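#include <Rcpp.h>
#include <R_ext/Rdynload.h>
#include <vector>
using namespace Rcpp;

// Compiled right-hand side for the deterministic ODE model, used through
// deSolve's compiled-code interface.  The active network description is
// staged from R (single-threaded use) before each integration.

namespace {
struct OdeSpec {
  int ns = 0, nr = 0;
  std::vector<double> stoich;          // ns x nr, column-major
  std::vector<std::vector<int>> fidx;  // per reaction: 0 = free conserved
  std::vector<std::vector<double>> fmul;
  std::vector<double> k;               // rate constant per reaction
  std::vector<int> fb_on;              // 1-based species, 0 = none
  std::vector<double> fb_kappa;
  int bound_idx = 0;                   // 1-based
  double u_tot = 0.0;
};
OdeSpec spec;
}

void set_ode_network(int ns, NumericMatrix stoich, List factors_idx,
                     List factors_mult, NumericVector rates,
                     IntegerVector fb_on, NumericVector fb_kappa,
                     int bound_idx, double u_tot) {
  spec.ns = ns;
  spec.nr = rates.size();
  spec.stoich.assign(stoich.begin(), stoich.end());
  spec.fidx.resize(spec.nr);
  spec.fmul.resize(spec.nr);
  for (int j = 0; j < spec.nr; ++j) {
    IntegerVector fi = factors_idx[j];
    NumericVector fm = factors_mult[j];
    spec.fidx[j].assign(fi.begin(), fi.end());
    spec.fmul[j].assign(fm.begin(), fm.end());
  }
  spec.k.assign(rates.begin(), rates.end());
  spec.fb_on.assign(fb_on.begin(), fb_on.end());
  spec.fb_kappa.assign(fb_kappa.begin(), fb_kappa.end());
  spec.bound_idx = bound_idx;
  spec.u_tot = u_tot;
}

extern "C" {

void mudrug_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip) {
  (void)neq; (void)t; (void)yout; (void)ip;
  const int ns = spec.ns, nr = spec.nr;
  double u_free = spec.bound_idx > 0
                      ? spec.u_tot - y[spec.bound_idx - 1] : 0.0;
  for (int i = 0; i < ns; ++i) ydot[i] = 0.0;
  for (int j = 0; j < nr; ++j) {
    double r = spec.k[j];
    for (size_t m = 0; m < spec.fidx[j].size(); ++m) {
      double c = spec.fidx[j][m] == 0 ? u_free : y[spec.fidx[j][m] - 1];
      double mult = spec.fmul[j][m];
      r *= (mult == 1.0) ? c : std::pow(c, mult);
    }
    if (spec.fb_on[j] > 0)
      r /= (1.0 + spec.fb_kappa[j] * y[spec.fb_on[j] - 1]);
    for (int i = 0; i < ns; ++i) ydot[i] += spec.stoich[i + j * ns] * r;
  }
}

}
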