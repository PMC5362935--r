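#include <Rcpp.h>
using namespace Rcpp;

// Per-sample voltage-clamp sweep integration.
//
// At every sample the membrane potential V satisfies
//   V = v_cmd - I_true(V) * Rs
// where I_true is the sum of a non-chloride leak (linear or exponential),
// the resting chloride conductance and the exchange-filtered agonist
// conductance, both reversing at E_Cl. Recording noise is added to the
// measured current only; it does not flow through Rs and does not load the
// cell. When coupled, [Cl-]i is advanced each sample by the chloride
// channel flux (and optionally a KCC2 term).
//
// Units: mV, pA, nS, s; rs in Mohm (1 pA * 1 Mohm = 1e-3 mV).
// [[Rcpp::export]]
List simulate_sweep_core(NumericVector v_cmd, double dt,
                         int leak_form,        // 0 linear, 1 exponential
                         double leak_g, double leak_erev,
                         double leak_a, double leak_b, double leak_c,
                         double g_cl, NumericVector g_ag_target,
                         double tau_exchange, double rs_mohm,
                         NumericVector noise,
                         bool couple, bool kcc2_on,
                         double cl_i0, double cl_o, double k_i, double k_o,
                         double temp, double g_kcc2, double v_equ,
                         NumericVector cl_schedule) {
  const bool use_sched = cl_schedule.size() > 0;
  const double R_GAS = 8.314, FARADAY = 96485.0;
  const int n = v_cmd.size();
  const double r = rs_mohm * 1e-3;              // mV per pA
  const double alpha = 1.0 - std::exp(-dt / tau_exchange);
  const double nern = 1000.0 * R_GAS * temp / FARADAY;          // mV
  const double cfac = 1e-12 * dt / (FARADAY * v_equ) * 1000.0;  // pA -> mM
  const double kfac = R_GAS * temp * g_kcc2 / v_equ * 1000.0 * dt;
  const double kratio = std::log(k_i / k_o);

  NumericVector i_meas(n), v_m(n), cl_i(n), g_ag(n);
  double cl = cl_i0;
  double g = 0.0;  // agonist conductance state
  double v = (n > 0) ? v_cmd[0] : 0.0;

  for (int i = 0; i < n; ++i) {
    if (use_sched) cl = cl_schedule[i];
    g += (g_ag_target[i] - g) * alpha;
    double e_cl = nern * std::log(cl / cl_o);
    double g_cl_tot = g_cl + g;

    if (leak_form == 0) {
      // fully linear: direct solve
      double num = v_cmd[i] + r * (leak_g * leak_erev + g_cl_tot * e_cl);
      v = num / (1.0 + r * (leak_g + g_cl_tot));
    } else {
      // fixed point with the exponential leak
      double v_prev = v;
      bool ok = false;
      for (int it = 0; it < 200; ++it) {
        double itrue = leak_a + leak_b * std::exp(v_prev / leak_c) +
                       g_cl_tot * (v_prev - e_cl);
        double v_new = v_cmd[i] - itrue * r;
        if (std::fabs(v_new - v_prev) < 1e-10) { v_prev = v_new; ok = true; break; }
        v_prev = v_new;
      }
      if (!ok) stop("series-resistance fixed point did not converge (pathological parameters)");
      v = v_prev;
    }

    double i_leak = (leak_form == 0)
      ? leak_g * (v - leak_erev)
      : leak_a + leak_b * std::exp(v / leak_c);
    double i_cl = g_cl_tot * (v - e_cl);
    double itrue = i_leak + i_cl;

    i_meas[i] = itrue + noise[i];
    v_m[i] = v;
    g_ag[i] = g;
    cl_i[i] = cl;

    if (couple) {
      double dcl = i_cl * cfac;
      if (kcc2_on)
        dcl -= kfac * (std::log(cl / cl_o) + kratio);
      cl += dcl;
      if (cl <= 0.0) stop("[Cl-]i became non-positive during sweep simulation");
    }
  }
  return List::create(_["i_pA"] = i_meas, _["v_m_mV"] = v_m,
                      _["cl_i_mM"] = cl_i, _["g_ag_nS"] = g_ag);
}
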