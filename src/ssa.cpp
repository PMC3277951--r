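#include <Rcpp.h>
#include <cstdint>
#include <random>
using namespace Rcpp;

// Direct-method Gillespie simulation of a mass-action network in molecule
// counts.  A self-contained 64-bit Mersenne-Twister stream (raw 53-bit
// uniforms, no library distributions) keeps trajectories bit-reproducible
// across platforms for a given seed.
//
// factors_idx/factors_mult describe each reaction's rate law: species index
// (1-based; 0 denotes the free conserved species utot_count - x[bound_idx]),
// with its multiplicity.  fb_on (1-based; 0 = none) and fb_kappa describe an
// inverse-linear feedback factor 1 / (1 + kappa * x[on]/omega) evaluated in
// concentration units.

static inline double runif53(std::mt19937_64 &gen) {
  return ((gen() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

static inline double falling(double n, int m) {
  double r = 1.0;
  for (int i = 0; i < m; ++i) r *= (n - i);
  return r;
}

List ssa_run_cpp(IntegerVector x0, IntegerMatrix stoich, NumericVector cvec,
                 List factors_idx, List factors_mult, List factors_fact,
                 IntegerVector fb_on, NumericVector fb_kappa, double omega,
                 double utot_count, int bound_idx, double t_end,
                 NumericVector grid, bool record_events, double seed,
                 double max_events) {
  const int ns = x0.size(), nr = cvec.size();
  std::vector<double> x(ns);
  for (int i = 0; i < ns; ++i) x[i] = x0[i];
  std::vector<std::vector<int>> fidx(nr), fmul(nr);
  std::vector<double> ffac(nr);
  for (int j = 0; j < nr; ++j) {
    IntegerVector fi = factors_idx[j], fm = factors_mult[j];
    fidx[j].assign(fi.begin(), fi.end());
    fmul[j].assign(fm.begin(), fm.end());
    ffac[j] = as<double>(factors_fact[j]);
  }
  // splitmix64 scrambling so that nearby integer seeds give unrelated streams
  uint64_t z = (uint64_t)seed + 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  std::mt19937_64 gen(z ^ (z >> 31));

  std::vector<double> a(nr);
  std::vector<double> ev_t;
  std::vector<int> ev_s;
  NumericMatrix grid_states(grid.size(), ns);
  int gi = 0;
  double t = 0.0, nev = 0.0;

  auto record_state = [&](double tnow) {
    // last-value-carried-forward: grid points strictly before the pending
    // jump take the pre-jump state
    while (gi < grid.size() && grid[gi] < tnow) {
      for (int i = 0; i < ns; ++i) grid_states(gi, i) = x[i];
      ++gi;
    }
  };
  if (record_events) {
    ev_t.push_back(0.0);
    for (int i = 0; i < ns; ++i) ev_s.push_back((int)x[i]);
  }

  for (;;) {
    double a0 = 0.0;
    for (int j = 0; j < nr; ++j) {
      double aj = cvec[j] * ffac[j];
      for (size_t m = 0; m < fidx[j].size(); ++m) {
        double cnt = fidx[j][m] == 0 ? (utot_count - x[bound_idx - 1])
                                     : x[fidx[j][m] - 1];
        aj *= falling(cnt, fmul[j][m]);
      }
      if (fb_on[j] > 0)
        aj /= (1.0 + fb_kappa[j] * x[fb_on[j] - 1] / omega);
      if (aj < -1e-12) stop("negative propensity (model inconsistency)");
      a[j] = aj > 0 ? aj : 0.0;
      a0 += a[j];
    }
    if (a0 <= 0.0) { t = t_end; break; }
    double tau = -std::log(runif53(gen)) / a0;
    if (t + tau > t_end) { t = t_end; break; }
    t += tau;
    record_state(t);
    // pick reaction
    double r = runif53(gen) * a0, cum = 0.0;
    int j = nr - 1;
    for (int jj = 0; jj < nr; ++jj) {
      cum += a[jj];
      if (r <= cum) { j = jj; break; }
    }
    for (int i = 0; i < ns; ++i) x[i] += stoich(i, j);
    if (record_events) {
      ev_t.push_back(t);
      for (int i = 0; i < ns; ++i) ev_s.push_back((int)x[i]);
    }
    nev += 1.0;
    if (nev > max_events) stop("SSA exceeded max_events");
  }
  // fill remaining grid points with the final state
  while (gi < grid.size()) {
    for (int i = 0; i < ns; ++i) grid_states(gi, i) = x[i];
    ++gi;
  }
  List out = List::create(_["grid_states"] = grid_states,
                          _["n_events"] = nev);
  if (record_events) {
    int ne = ev_t.size();
    NumericVector tt(ev_t.begin(), ev_t.end());
    IntegerMatrix st(ne, ns);
    for (int e = 0; e < ne; ++e)
      for (int i = 0; i < ns; ++i) st(e, i) = ev_s[(size_t)e * ns + i];
    out["event_times"] = tt;
    out["event_states"] = st;
  }
  return out;
}
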