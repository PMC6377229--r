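// Multi-compartment cable integrator for the model DSGC.
//
// Units: mV, ms, nA, uS, nF (so g*V -> nA and C*dV/dt -> nA).
// Tree solve uses Hines ordering (parent index < child index), one
// backward-elimination / forward-substitution pass per time step.
// Gating variables advance by Rush-Larsen exponential updates; synaptic
// conductances are event-driven bi-exponentials kept as two decaying
// states per (compartment, transmitter) channel.

#include <Rcpp.h>
#include <cmath>
#include <random>
using namespace Rcpp;

namespace {

inline double safe_exp_ratio(double x, double y) {
  // returns x / (1 - exp(-x/y)); near x = 0 the limit is y
  double r = x / y;
  if (std::fabs(r) < 1e-6) return y * (1.0 + r / 2.0);
  return x / (1.0 - std::exp(-r));
}

// canonical HH sodium/potassium rate functions (voltage in mV, rates in 1/ms)
inline double am(double v) { return 0.1 * safe_exp_ratio(v + 40.0, 10.0); }
inline double bm(double v) { return 4.0 * std::exp(-(v + 65.0) / 18.0); }
inline double ah(double v) { return 0.07 * std::exp(-(v + 65.0) / 20.0); }
inline double bh(double v) { return 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0)); }
inline double an(double v) { return 0.01 * safe_exp_ratio(v + 55.0, 10.0); }
inline double bn(double v) { return 0.125 * std::exp(-(v + 65.0) / 80.0); }

// slow non-inactivating K ("delayed rectifier" at low density)
inline double winf(double v, double half) {
  return 1.0 / (1.0 + std::exp(-(v - half) / 10.0));
}
inline double wtau(double v, double half) {
  return 50.0 / (std::exp((v - half) / 40.0) + std::exp(-(v - half) / 40.0));
}

} // namespace

// [[Rcpp::export]]
List cable_sim_cpp(IntegerVector parent,
                   NumericVector cap_nf,
                   NumericVector g_ax_us,
                   NumericVector g_leak_us,
                   double e_leak,
                   NumericVector g_na_us,
                   NumericVector g_k_us,
                   NumericVector g_km_us,
                   double e_na, double e_k,
                   double na_shift_mv, double k_shift_mv, double km_half_mv,
                   IntegerVector chan_comp,
                   NumericVector chan_tau_r,
                   NumericVector chan_tau_d,
                   NumericVector chan_erev,
                   IntegerVector ev_chan,
                   NumericVector ev_time,
                   NumericVector ev_weight_us,
                   double dt, int nsteps, double v_init,
                   int mode, double hold_mv,
                   NumericVector i_inj_soma_na,
                   NumericVector noise_sigma_na,
                   double noise_tau_ms,
                   int noise_seed,
                   bool record_all) {
  const int n = parent.size();
  const int nchan = chan_comp.size();
  const int nev = ev_chan.size();
  const bool vc = (mode == 1);

  std::vector<double> v(n, v_init), m(n), h(n), ng(n), w(n);
  for (int i = 0; i < n; ++i) {
    double vna = v[i] - na_shift_mv, vk = v[i] - k_shift_mv;
    m[i] = am(vna) / (am(vna) + bm(vna));
    h[i] = ah(vna) / (ah(vna) + bh(vna));
    ng[i] = an(vk) / (an(vk) + bn(vk));
    w[i] = winf(v[i], km_half_mv);
  }
  if (vc) v[0] = hold_mv;

  // synaptic channel state: g = b - a (both decay exponentially)
  std::vector<double> sa(nchan, 0.0), sb(nchan, 0.0);
  std::vector<double> dec_a(nchan), dec_b(nchan);
  for (int c = 0; c < nchan; ++c) {
    dec_a[c] = std::exp(-dt / chan_tau_r[c]);
    dec_b[c] = std::exp(-dt / chan_tau_d[c]);
  }

  // Ornstein-Uhlenbeck noise current per compartment
  const bool noise_on = noise_sigma_na.size() == n;
  std::vector<double> inoise(n, 0.0);
  double ou_decay = std::exp(-dt / noise_tau_ms);
  double ou_scale = std::sqrt(1.0 - ou_decay * ou_decay);
  std::mt19937_64 rng(static_cast<unsigned long long>(noise_seed));
  auto unif = [&rng]() {
    return (static_cast<double>(rng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  };
  bool have_spare = false; double spare = 0.0;
  auto gauss = [&]() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    have_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  };

  const bool has_inj = i_inj_soma_na.size() >= nsteps;

  NumericVector trace(nsteps + 1);
  NumericMatrix vall;
  if (record_all) vall = NumericMatrix(nsteps + 1, n);
  if (vc) {
    // initial electrode current: ionic current at the hold with resting
    // gates and all compartments at v_init (axial terms cancel at t = 0
    // when v_init equals the hold potential)
    double vv = v[0];
    double gna0 = g_na_us[0] * m[0] * m[0] * m[0] * h[0];
    double gk0 = g_k_us[0] * ng[0] * ng[0] * ng[0] * ng[0];
    double gkm0 = g_km_us[0] * w[0];
    double i0 = g_leak_us[0] * (vv - e_leak) + gna0 * (vv - e_na) +
      (gk0 + gkm0) * (vv - e_k);
    for (int i = 1; i < n; ++i)
      if (parent[i] == 0) i0 += g_ax_us[i] * (vv - v[i]);
    trace[0] = i0 * 1000.0;
  } else {
    trace[0] = v[0];
  }
  if (record_all) for (int i = 0; i < n; ++i) vall(0, i) = v[i];

  std::vector<double> diag(n), rhs(n), gsyn_sum(n), isyn_e(n);
  int ev_ptr = 0;

  for (int step = 0; step < nsteps; ++step) {
    double t_next = (step + 1) * dt;

    // 1. gates (Rush-Larsen at current voltage)
    for (int i = 0; i < n; ++i) {
      double vna = v[i] - na_shift_mv, vk = v[i] - k_shift_mv;
      if (g_na_us[i] > 0.0) {
        double a, b, tau, inf;
        a = am(vna); b = bm(vna); tau = 1.0 / (a + b); inf = a * tau;
        m[i] = inf + (m[i] - inf) * std::exp(-dt / tau);
        a = ah(vna); b = bh(vna); tau = 1.0 / (a + b); inf = a * tau;
        h[i] = inf + (h[i] - inf) * std::exp(-dt / tau);
      }
      if (g_k_us[i] > 0.0) {
        double a = an(vk), b = bn(vk), tau = 1.0 / (a + b), inf = a * tau;
        ng[i] = inf + (ng[i] - inf) * std::exp(-dt / tau);
      }
      if (g_km_us[i] > 0.0) {
        double tau = wtau(v[i], km_half_mv), inf = winf(v[i], km_half_mv);
        w[i] = inf + (w[i] - inf) * std::exp(-dt / tau);
      }
    }

    // 2. synaptic states: decay, then fold in events inside (t, t+dt]
    for (int c = 0; c < nchan; ++c) { sa[c] *= dec_a[c]; sb[c] *= dec_b[c]; }
    while (ev_ptr < nev && ev_time[ev_ptr] <= t_next) {
      int c = ev_chan[ev_ptr];
      double rem = t_next - ev_time[ev_ptr]; // partial decay since onset
      sa[c] += ev_weight_us[ev_ptr] * std::exp(-rem / chan_tau_r[c]);
      sb[c] += ev_weight_us[ev_ptr] * std::exp(-rem / chan_tau_d[c]);
      ++ev_ptr;
    }
    std::fill(gsyn_sum.begin(), gsyn_sum.end(), 0.0);
    std::fill(isyn_e.begin(), isyn_e.end(), 0.0);
    for (int c = 0; c < nchan; ++c) {
      double g = sb[c] - sa[c];
      if (g < 0.0) g = 0.0;
      gsyn_sum[chan_comp[c]] += g;
      isyn_e[chan_comp[c]] += g * chan_erev[c];
    }

    // 3. noise
    if (noise_on)
      for (int i = 0; i < n; ++i)
        inoise[i] = inoise[i] * ou_decay + noise_sigma_na[i] * ou_scale * gauss();

    // 4. assemble implicit voltage system
    for (int i = 0; i < n; ++i) {
      double gna = g_na_us[i] * m[i] * m[i] * m[i] * h[i];
      double gk = g_k_us[i] * ng[i] * ng[i] * ng[i] * ng[i];
      double gkm = g_km_us[i] * w[i];
      double gtot = g_leak_us[i] + gna + gk + gkm + gsyn_sum[i];
      double esum = g_leak_us[i] * e_leak + gna * e_na + (gk + gkm) * e_k +
        isyn_e[i];
      diag[i] = cap_nf[i] / dt + gtot;
      rhs[i] = cap_nf[i] / dt * v[i] + esum + inoise[i];
      if (i == 0 && has_inj && !vc) rhs[i] += i_inj_soma_na[step];
      if (parent[i] >= 0) diag[i] += g_ax_us[i];
    }
    for (int i = 1; i < n; ++i)
      if (parent[i] >= 0) diag[parent[i]] += g_ax_us[i];

    // 5. Hines solve (parent index < child index by construction)
    for (int i = n - 1; i >= 1; --i) {
      int p = parent[i];
      double f = g_ax_us[i] / diag[i];
      diag[p] -= g_ax_us[i] * f;
      rhs[p] += rhs[i] * f;
    }
    if (vc) v[0] = hold_mv; else v[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i)
      v[i] = (rhs[i] + g_ax_us[i] * v[parent[i]]) / diag[i];

    if (!std::isfinite(v[0]))
      stop("numerical instability: NaN soma voltage at t=%.3f ms (dt=%g)",
           t_next, dt);

    if (vc) {
      // electrode current holding the soma: ionic + synaptic + axial - noise
      double vv = v[0];
      double gna = g_na_us[0] * m[0] * m[0] * m[0] * h[0];
      double gk = g_k_us[0] * ng[0] * ng[0] * ng[0] * ng[0];
      double gkm = g_km_us[0] * w[0];
      double iion = g_leak_us[0] * (vv - e_leak) + gna * (vv - e_na) +
        (gk + gkm) * (vv - e_k) + gsyn_sum[0] * vv - isyn_e[0];
      double iax = 0.0;
      for (int i = 1; i < n; ++i)
        if (parent[i] == 0) iax += g_ax_us[i] * (vv - v[i]);
      trace[step + 1] = (iion + iax - inoise[0]) * 1000.0; // nA -> pA
    } else {
      trace[step + 1] = v[0];
    }
    if (record_all) for (int i = 0; i < n; ++i) vall(step + 1, i) = v[i];
  }

  List out = List::create(_["trace"] = trace);
  if (record_all) out["voltages"] = vall;
  return out;
}
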