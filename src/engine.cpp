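// Fixed-step RK4 integrator for the closed-loop trial: elbow plant with two
// linear Hill muscles, two miniature-Hill muscle spindles with gamma drive,
// two Golgi tendon organs, 12 leaky-integrator non-spiking neurons with
// graded synapses, and piecewise-constant SET/GO command inputs.
//
// State vector y (length 20):
//   y[0..11]  membrane potentials of the 12 dynamic neurons (mV)
//   y[12,13]  muscle membrane potentials flexor/extensor (mV)
//   y[14,15]  muscle serial tensions flexor/extensor (N)
//   y[16,17]  spindle serial tensions flexor/extensor (N)
//   y[18]     elbow angle (deg), y[19] angular velocity (deg/s)
//
// The R reference engine (run_trial(engine = "reference")) implements the
// identical update; a regression test asserts agreement.

#include <Rcpp.h>
using namespace Rcpp;

struct Engine {
  // commands
  double set_time, go_time;
  std::vector<double> iset, igo;           // 12 each
  // neurons
  std::vector<double> rest, tau, gl;       // 12 each
  std::vector<int> clamp_mask;             // 16 nodes
  std::vector<double> clamp_value;         // 16 nodes
  // synapses
  std::vector<int> pre, post, suppressed;
  std::vector<double> gmax, thr, sat, erev, gain;
  // muscles (index 0 flexor, 1 extensor)
  double l_int[2], l_slope[2];             // m, m/deg
  double mB[2], mKpe[2], mKse[2], mslack[2], mmaxT[2];
  double lt_w[2], lt_c[2], st_amp[2], st_k[2], st_x0[2], st_y0[2];
  // spindles
  double sB[2], sKpe[2], sKse[2], sslack[2], smaxT[2];
  double kT[2], kdT[2], ia_rest[2], g_gain[2], g_thr[2];
  // gto
  double kB[2], ib_rest[2], ib_sat[2];
  // muscle-membrane drive synapse
  double d_gmax, d_thr, d_sat, d_erev, d_rest, d_tau;
  // joint
  double inertia, b_joint, r_flex, r_ext, angle_min, angle_max;

  static double hill_deriv(double T, double dx, double v, double A,
                           double B, double Kpe, double Kse) {
    double dT = (Kse / B) * (Kpe * dx + B * v - (1.0 + Kpe / Kse) * T + A);
    if (T <= 0.0 && dT < 0.0) dT = 0.0;
    return dT;
  }

  // Computes dy and, if aff != nullptr, the four afferent node potentials
  // (Flx1a, Ext1a, Flx1b, Ext1b).
  void deriv(double t, const double* y, double* dy, double* aff_out) const {
    bool set_on = t >= set_time - 1e-12;
    bool go_on = t >= go_time - 1e-12;

    double theta = y[18], omega = y[19];
    double L[2], dL[2];
    for (int m = 0; m < 2; ++m) {
      L[m] = l_int[m] + l_slope[m] * theta;
      dL[m] = l_slope[m] * omega;
    }

    // spindle tension derivatives and Ia potentials
    double dTsp[2], ia[2];
    for (int m = 0; m < 2; ++m) {
      double vg = clamp_mask[2 + m] ? clamp_value[2 + m] : y[2 + m];
      double act = g_gain[m] * std::max(0.0, vg - g_thr[m]);
      if (act > smaxT[m]) act = smaxT[m];
      double dx = std::max(0.0, L[m] - sslack[m]);
      double T = y[16 + m];
      dTsp[m] = hill_deriv(T, dx, dL[m], act, sB[m], sKpe[m], sKse[m]);
      ia[m] = (T <= 0.0) ? ia_rest[m]
                         : ia_rest[m] + kT[m] * T + kdT[m] * dTsp[m];
    }
    // Ib potentials
    double ib[2];
    for (int m = 0; m < 2; ++m) {
      double T = std::max(0.0, y[14 + m]);
      ib[m] = ib_rest[m] + kB[m] * T;
      if (ib[m] > ib_sat[m]) ib[m] = ib_sat[m];
    }

    // node potential table (12 neurons + Flx1a, Ext1a, Flx1b, Ext1b)
    double P[16];
    for (int i = 0; i < 12; ++i)
      P[i] = clamp_mask[i] ? clamp_value[i] : y[i];
    P[12] = clamp_mask[12] ? clamp_value[12] : ia[0];
    P[13] = clamp_mask[13] ? clamp_value[13] : ia[1];
    P[14] = clamp_mask[14] ? clamp_value[14] : ib[0];
    P[15] = clamp_mask[15] ? clamp_value[15] : ib[1];
    if (aff_out) {
      aff_out[0] = P[12]; aff_out[1] = P[13];
      aff_out[2] = P[14]; aff_out[3] = P[15];
    }

    // synaptic conductances accumulated per postsynaptic neuron
    double G[12] = {0}, GE[12] = {0};
    if (set_on) {
      for (size_t s = 0; s < pre.size(); ++s) {
        if (suppressed[s] || gain[s] <= 0.0) continue;
        double frac = (P[pre[s]] - thr[s]) / (sat[s] - thr[s]);
        if (frac <= 0.0) continue;
        if (frac > 1.0) frac = 1.0;
        double g = gain[s] * gmax[s] * frac;
        G[post[s]] += g;
        GE[post[s]] += g * erev[s];
      }
    }

    // neuron updates
    for (int i = 0; i < 12; ++i) {
      if (clamp_mask[i]) { dy[i] = 0.0; continue; }
      double I = (set_on ? iset[i] : 0.0) + (go_on ? igo[i] : 0.0);
      double C = tau[i] * gl[i];
      dy[i] = (gl[i] * (rest[i] - y[i]) + GE[i] - G[i] * y[i] + I) / C;
    }

    // muscle membranes driven by their alpha MNs (fixed plant coupling)
    for (int m = 0; m < 2; ++m) {
      double frac = (P[m] - d_thr) / (d_sat - d_thr);
      if (frac < 0.0) frac = 0.0;
      if (frac > 1.0) frac = 1.0;
      double g = d_gmax * frac;
      double C = d_tau * 1.0;
      dy[12 + m] = ((d_rest - y[12 + m]) + g * (d_erev - y[12 + m])) / C;
    }

    // muscle tensions
    for (int m = 0; m < 2; ++m) {
      double stv = st_amp[m] / (1.0 + std::exp(st_k[m] * (st_x0[m] - y[12 + m]))) + st_y0[m];
      if (stv < 0.0) stv = 0.0;
      double ltf = 1.0 - std::pow((L[m] - lt_c[m]) / lt_w[m], 2.0);
      if (ltf < 0.0) ltf = 0.0;
      double A = stv * ltf;
      if (A > mmaxT[m]) A = mmaxT[m];
      double dx = std::max(0.0, L[m] - mslack[m]);
      dy[14 + m] = hill_deriv(y[14 + m], dx, dL[m], A, mB[m], mKpe[m], mKse[m]);
    }
    for (int m = 0; m < 2; ++m)
      dy[16 + m] = dTsp[m];

    // joint
    double torque = r_flex * std::max(0.0, y[14]) -
                    r_ext * std::max(0.0, y[15]) -
                    b_joint * omega * M_PI / 180.0;
    dy[18] = omega;
    dy[19] = torque / inertia * 180.0 / M_PI;
  }
};

static std::vector<double> as_dvec(SEXP x) {
  NumericVector v(x);
  return std::vector<double>(v.begin(), v.end());
}
static std::vector<int> as_ivec(SEXP x) {
  IntegerVector v(x);
  return std::vector<int>(v.begin(), v.end());
}

// [[Rcpp::export]]
List sim_core(List pars) {
  Engine e;
  e.set_time = as<double>(pars["set_time"]);
  e.go_time = as<double>(pars["go_time"]);
  e.iset = as_dvec(pars["iset"]);
  e.igo = as_dvec(pars["igo"]);
  e.rest = as_dvec(pars["rest"]);
  e.tau = as_dvec(pars["tau"]);
  e.gl = as_dvec(pars["gl"]);
  e.clamp_mask = as_ivec(pars["clamp_mask"]);
  e.clamp_value = as_dvec(pars["clamp_value"]);
  e.pre = as_ivec(pars["pre"]);
  e.post = as_ivec(pars["post"]);
  e.suppressed = as_ivec(pars["suppressed"]);
  e.gmax = as_dvec(pars["gmax"]);
  e.thr = as_dvec(pars["thr"]);
  e.sat = as_dvec(pars["sat"]);
  e.erev = as_dvec(pars["erev"]);
  e.gain = as_dvec(pars["gain"]);

  NumericVector tmp;
  #define LOAD2(field, name) { tmp = pars[name]; e.field[0] = tmp[0]; e.field[1] = tmp[1]; }
  LOAD2(l_int, "l_int") LOAD2(l_slope, "l_slope")
  LOAD2(mB, "mB") LOAD2(mKpe, "mKpe") LOAD2(mKse, "mKse")
  LOAD2(mslack, "mslack") LOAD2(mmaxT, "mmaxT")
  LOAD2(lt_w, "lt_w") LOAD2(lt_c, "lt_c")
  LOAD2(st_amp, "st_amp") LOAD2(st_k, "st_k")
  LOAD2(st_x0, "st_x0") LOAD2(st_y0, "st_y0")
  LOAD2(sB, "sB") LOAD2(sKpe, "sKpe") LOAD2(sKse, "sKse")
  LOAD2(sslack, "sslack") LOAD2(smaxT, "smaxT")
  LOAD2(kT, "kT") LOAD2(kdT, "kdT") LOAD2(ia_rest, "ia_rest")
  LOAD2(g_gain, "g_gain") LOAD2(g_thr, "g_thr")
  LOAD2(kB, "kB") LOAD2(ib_rest, "ib_rest") LOAD2(ib_sat, "ib_sat")
  #undef LOAD2

  e.d_gmax = as<double>(pars["d_gmax"]);
  e.d_thr = as<double>(pars["d_thr"]);
  e.d_sat = as<double>(pars["d_sat"]);
  e.d_erev = as<double>(pars["d_erev"]);
  e.d_rest = as<double>(pars["d_rest"]);
  e.d_tau = as<double>(pars["d_tau"]);
  e.inertia = as<double>(pars["inertia"]);
  e.b_joint = as<double>(pars["b_joint"]);
  e.r_flex = as<double>(pars["r_flex"]);
  e.r_ext = as<double>(pars["r_ext"]);
  e.angle_min = as<double>(pars["angle_min"]);
  e.angle_max = as<double>(pars["angle_max"]);

  double dt = as<double>(pars["dt"]);
  int n_steps = as<int>(pars["n_steps"]);
  int stride = as<int>(pars["record_stride"]);
  std::vector<double> y = as_dvec(pars["y0"]);

  int n_rec = n_steps / stride + 1;
  NumericMatrix out(n_rec, 22);
  NumericVector time(n_rec);
  bool ok = true;

  double dy1[20], dy2[20], dy3[20], dy4[20], yt[20], aff[4];
  int rec = 0;
  for (int step = 0; step <= n_steps; ++step) {
    double t = step * dt;
    if (step % stride == 0) {
      e.deriv(t, y.data(), dy1, aff);   // afferents at the recorded state
      time[rec] = t;
      out(rec, 0) = y[18];              // angle
      out(rec, 1) = y[19];              // speed
      for (int i = 0; i < 12; ++i)
        out(rec, 2 + i) = e.clamp_mask[i] ? e.clamp_value[i] : y[i];
      for (int i = 0; i < 4; ++i) out(rec, 14 + i) = aff[i];
      out(rec, 18) = y[12]; out(rec, 19) = y[13];
      out(rec, 20) = std::max(0.0, y[14]); out(rec, 21) = std::max(0.0, y[15]);
      ++rec;
    }
    if (step == n_steps) break;

    e.deriv(t, y.data(), dy1, nullptr);
    for (int i = 0; i < 20; ++i) yt[i] = y[i] + dt / 2 * dy1[i];
    e.deriv(t + dt / 2, yt, dy2, nullptr);
    for (int i = 0; i < 20; ++i) yt[i] = y[i] + dt / 2 * dy2[i];
    e.deriv(t + dt / 2, yt, dy3, nullptr);
    for (int i = 0; i < 20; ++i) yt[i] = y[i] + dt * dy3[i];
    e.deriv(t + dt, yt, dy4, nullptr);
    for (int i = 0; i < 20; ++i)
      y[i] += dt / 6 * (dy1[i] + 2 * dy2[i] + 2 * dy3[i] + dy4[i]);

    // clamps and hard constraints
    for (int i = 0; i < 12; ++i)
      if (e.clamp_mask[i]) y[i] = e.clamp_value[i];
    for (int m = 0; m < 4; ++m)
      if (y[14 + m] < 0.0) y[14 + m] = 0.0;
    if (y[18] <= e.angle_min) {
      y[18] = e.angle_min;
      if (y[19] < 0.0) y[19] = 0.0;
    } else if (y[18] >= e.angle_max) {
      y[18] = e.angle_max;
      if (y[19] > 0.0) y[19] = 0.0;
    }
    bool fin = true;
    for (int i = 0; i < 20; ++i)
      if (!std::isfinite(y[i])) { fin = false; break; }
    if (!fin) { ok = false; break; }
  }

  return List::create(_["time"] = time, _["channels"] = out,
                      _["ok"] = ok, _["n_recorded"] = rec);
}
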