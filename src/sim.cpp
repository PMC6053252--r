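// Core integrators for the point-neuron and soma-dendrite models.
//
// Synaptic gates are not part of the ODE state: between events they decay as
// exact exponentials, and integration is restarted at every event time so the
// reset discontinuity never crosses a step.  The stepper is an embedded
// Dormand-Prince 5(4) pair with PI-free step control; spikes are detected on
// the soma voltage as upward threshold crossings with a lockout interval.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Params {
  // membrane
  double C, g_L, g_K, g_Na, g_A;
  double V_L, V_K, V_Na;
  // gating: slope entries are magnitudes, direction fixed by physiology
  double phi_n, theta_n, sigma_n;
  double phi_a, theta_a, sigma_a, tau_a;
  double phi_b, theta_b, sigma_b, tau_b;
  // synapses
  double g_SynE, g_SynI, V_E, V_I, beta_E, beta_I;
  bool instantaneous_a;
  // cable
  int n_comp, cpt_in, cpt_inhib;
  double g_L_dend, g_Ax;
};

Params read_params(const List& p) {
  Params q;
  q.C = p["C"]; q.g_L = p["g_L"]; q.g_K = p["g_K"]; q.g_Na = p["g_Na"];
  q.g_A = p["g_A"];
  q.V_L = p["V_L"]; q.V_K = p["V_K"]; q.V_Na = p["V_Na"];
  q.phi_n = p["phi_n"]; q.theta_n = p["theta_n"]; q.sigma_n = p["sigma_n"];
  q.phi_a = p["phi_a"]; q.theta_a = p["theta_a"]; q.sigma_a = p["sigma_a"];
  q.tau_a = p["tau_a"];
  q.phi_b = p["phi_b"]; q.theta_b = p["theta_b"]; q.sigma_b = p["sigma_b"];
  q.tau_b = p["tau_b"];
  q.g_SynE = p["g_SynE"]; q.g_SynI = p["g_SynI"];
  q.V_E = p["V_E"]; q.V_I = p["V_I"];
  q.beta_E = p["beta_E"]; q.beta_I = p["beta_I"];
  q.instantaneous_a = as<bool>(p["instantaneous_a"]);
  q.n_comp = p.containsElementNamed("n_comp") ? as<int>(p["n_comp"]) : 10;
  q.cpt_in = p.containsElementNamed("cpt_in") ? as<int>(p["cpt_in"]) : 1;
  q.cpt_inhib = p.containsElementNamed("cpt_inhib") ? as<int>(p["cpt_inhib"]) : 0;
  q.g_L_dend = p.containsElementNamed("g_L_dend") ? as<double>(p["g_L_dend"]) : 0.1;
  q.g_Ax = p.containsElementNamed("g_Ax") ? as<double>(p["g_Ax"]) : 10.0;
  return q;
}

inline double m_inf(double V)  { return 1.0 / (1.0 + std::exp(-(V + 30.0) / 15.0)); }
inline double tau_n_fun(double V) { return 1.0 + 100.0 / (1.0 + std::exp((V + 80.0) / 26.0)); }
inline double n_inf(const Params& p, double V) {
  return 1.0 / (1.0 + std::exp(-(V - p.theta_n) / p.sigma_n));
}
inline double a_inf(const Params& p, double V) {
  return 1.0 / (1.0 + std::exp(-(V - p.theta_a) / p.sigma_a));
}
inline double b_inf(const Params& p, double V) {
  return 1.0 / (1.0 + std::exp((V - p.theta_b) / p.sigma_b));
}

// Point model right-hand side.  State: V, n, a, b (a slot inert when
// activation is instantaneous).
void rhs_point(const Params& p, double /*t*/, const double* y, double* dy,
               double sE, double sI) {
  const double V = y[0], n = y[1], b = y[3];
  const double a = p.instantaneous_a ? a_inf(p, V) : y[2];
  const double m = m_inf(V);
  const double I_L  = p.g_L * (V - p.V_L);
  const double I_K  = p.g_K * n * n * n * n * (V - p.V_K);
  const double I_A  = p.g_A * a * a * a * b * (V - p.V_K);
  const double I_Na = p.g_Na * m * m * m * (1.0 - n) * (V - p.V_Na);
  const double I_E  = p.g_SynE * sE * (V - p.V_E);
  const double I_I  = p.g_SynI * sI * (V - p.V_I);
  dy[0] = (-I_L - I_K - I_A - I_Na - I_E - I_I) / p.C;
  dy[1] = p.phi_n * (n_inf(p, V) - n) / tau_n_fun(V);
  dy[2] = p.instantaneous_a ? 0.0 : p.phi_a * (a_inf(p, V) - y[2]) / p.tau_a;
  dy[3] = p.phi_b * (b_inf(p, V) - b) / p.tau_b;
}

// Cable right-hand side.  State: V_1..V_nc, n, a, b.  Compartment 1 is the
// soma (all voltage-gated currents); 2..nc are passive with the dendritic
// leak.  Excitation enters at compartment cpt_in + 1; inhibition at the soma
// (cpt_inhib = 0) or at compartment cpt_inhib + 1.
void rhs_cable(const Params& p, double /*t*/, const double* y, double* dy,
               double sE, double sI) {
  const int nc = p.n_comp;
  const double n = y[nc], b = y[nc + 2];
  const double V1 = y[0];
  const double a = p.instantaneous_a ? a_inf(p, V1) : y[nc + 1];
  const double m = m_inf(V1);
  const int exc_cpt = p.cpt_in;                       // 0-based index cpt_in
  const int inh_cpt = p.cpt_inhib;                    // 0-based, 0 = soma
  for (int j = 0; j < nc; ++j) {
    const double V = y[j];
    double I_ax;
    if (j == 0)            I_ax = p.g_Ax * (y[0] - y[1]);
    else if (j == nc - 1)  I_ax = p.g_Ax * (y[nc - 1] - y[nc - 2]);
    else                   I_ax = p.g_Ax * (-y[j - 1] + 2.0 * V - y[j + 1]);
    double I_tot;
    if (j == 0) {
      const double I_L  = p.g_L * (V - p.V_L);
      const double I_K  = p.g_K * n * n * n * n * (V - p.V_K);
      const double I_A  = p.g_A * a * a * a * b * (V - p.V_K);
      const double I_Na = p.g_Na * m * m * m * (1.0 - n) * (V - p.V_Na);
      I_tot = I_L + I_K + I_A + I_Na + I_ax;
    } else {
      I_tot = p.g_L_dend * (V - p.V_L) + I_ax;
    }
    if (j == exc_cpt) I_tot += p.g_SynE * sE * (V - p.V_E);
    if (j == inh_cpt) I_tot += p.g_SynI * sI * (V - p.V_I);
    dy[j] = -I_tot / p.C;
  }
  dy[nc]     = p.phi_n * (n_inf(p, V1) - n) / tau_n_fun(V1);
  dy[nc + 1] = p.instantaneous_a ? 0.0 : p.phi_a * (a_inf(p, V1) - y[nc + 1]) / p.tau_a;
  dy[nc + 2] = p.phi_b * (b_inf(p, V1) - b) / p.tau_b;
}

// Dormand-Prince 5(4) coefficients.
const double c2 = 1.0/5, c3 = 3.0/10, c4 = 4.0/5, c5 = 8.0/9;
const double a21 = 1.0/5;
const double a31 = 3.0/40, a32 = 9.0/40;
const double a41 = 44.0/45, a42 = -56.0/15, a43 = 32.0/9;
const double a51 = 19372.0/6561, a52 = -25360.0/2187, a53 = 64448.0/6561,
             a54 = -212.0/729;
const double a61 = 9017.0/3168, a62 = -355.0/33, a63 = 46732.0/5247,
             a64 = 49.0/176, a65 = -5103.0/18656;
const double b1 = 35.0/384, b3 = 500.0/1113, b4 = 125.0/192,
             b5 = -2187.0/6784, b6 = 11.0/84;
const double e1 = b1 - 5179.0/57600, e3 = b3 - 7571.0/16695,
             e4 = b4 - 393.0/640, e5 = b5 + 92097.0/339200,
             e6 = b6 - 187.0/2100, e7 = -1.0/40;

struct Event { double t; int kind; };  // kind: 0 = excitatory, 1 = inhibitory

List integrate_model(const Params& p, bool cable,
                     NumericVector tE, NumericVector tI,
                     NumericVector y0, double duration, double transient,
                     double spike_threshold, double lockout,
                     double abstol, double reltol, double record_dt) {
  const int dim = cable ? p.n_comp + 3 : 4;
  if ((int)y0.size() != dim) stop("initial state has wrong dimension");
  if (cable && (p.cpt_in < 1 || p.cpt_in > p.n_comp - 1))
    stop("cpt_in out of range");
  if (cable && (p.cpt_inhib < 0 || p.cpt_inhib > p.n_comp - 1))
    stop("cpt_inhib out of range");

  // merged event list, restricted to [0, duration]
  std::vector<Event> ev;
  ev.reserve(tE.size() + tI.size());
  for (double t : tE) if (t >= 0 && t <= duration) ev.push_back({t, 0});
  for (double t : tI) if (t >= 0 && t <= duration) ev.push_back({t, 1});
  std::stable_sort(ev.begin(), ev.end(),
                   [](const Event& a, const Event& b) { return a.t < b.t; });

  std::vector<double> y(y0.begin(), y0.end()), ynew(dim), ytmp(dim);
  std::vector<double> k1(dim), k2(dim), k3(dim), k4(dim), k5(dim), k6(dim),
                      k7(dim);

  double t = 0.0;
  double sE = 0.0, sI = 0.0;       // gate values at the running reference time
  double t_gate = 0.0;             // reference time for sE, sI
  std::size_t iev = 0;

  std::vector<double> spikes;
  double last_spike = -1e18;
  double b_int = 0.0, b_t0 = transient;  // time integral of b beyond transient
  const int b_idx = cable ? p.n_comp + 2 : 3;

  // recording
  std::vector<double> rec_t;
  std::vector<std::vector<double>> rec_y;
  double next_rec = 0.0;
  const bool recording = record_dt > 0;
  if (recording) { rec_t.push_back(0.0); rec_y.push_back(y); next_rec = record_dt; }

  auto call_rhs = [&](double tt, const double* yy, double* dyy) {
    const double dtg = tt - t_gate;
    const double se = sE * std::exp(-p.beta_E * dtg);
    const double si = sI * std::exp(-p.beta_I * dtg);
    if (cable) rhs_cable(p, tt, yy, dyy, se, si);
    else       rhs_point(p, tt, yy, dyy, se, si);
  };

  long n_steps = 0, n_reject = 0;
  const long max_steps = 200000000L;

  while (t < duration) {
    // apply any events at the current time, then find next breakpoint
    while (iev < ev.size() && ev[iev].t <= t + 1e-12) {
      const double dtg = ev[iev].t - t_gate;
      sE *= std::exp(-p.beta_E * dtg);
      sI *= std::exp(-p.beta_I * dtg);
      t_gate = ev[iev].t;
      if (ev[iev].kind == 0) sE = 1.0; else sI = 1.0;
      ++iev;
    }
    double t_seg_end = duration;
    if (iev < ev.size()) t_seg_end = std::min(t_seg_end, ev[iev].t);

    // integrate the smooth segment [t, t_seg_end]
    double h = std::min(0.05, t_seg_end - t);
    call_rhs(t, y.data(), k1.data());  // FSAL seed
    while (t < t_seg_end - 1e-12) {
      if (h > t_seg_end - t) h = t_seg_end - t;
      if (++n_steps > max_steps) stop("integration failure near t = %f ms", t);

      for (int i = 0; i < dim; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
      call_rhs(t + c2 * h, ytmp.data(), k2.data());
      for (int i = 0; i < dim; ++i)
        ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
      call_rhs(t + c3 * h, ytmp.data(), k3.data());
      for (int i = 0; i < dim; ++i)
        ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
      call_rhs(t + c4 * h, ytmp.data(), k4.data());
      for (int i = 0; i < dim; ++i)
        ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                              a54 * k4[i]);
      call_rhs(t + c5 * h, ytmp.data(), k5.data());
      for (int i = 0; i < dim; ++i)
        ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                              a64 * k4[i] + a65 * k5[i]);
      call_rhs(t + h, ytmp.data(), k6.data());
      for (int i = 0; i < dim; ++i)
        ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                              b5 * k5[i] + b6 * k6[i]);
      call_rhs(t + h, ynew.data(), k7.data());

      double err = 0.0;
      for (int i = 0; i < dim; ++i) {
        const double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                               e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
        const double sc = abstol + reltol * std::max(std::fabs(y[i]),
                                                     std::fabs(ynew[i]));
        const double r = ei / sc;
        err += r * r;
      }
      err = std::sqrt(err / dim);
      if (!std::isfinite(err)) { h *= 0.25; ++n_reject; continue; }

      if (err <= 1.0) {  // accept
        const double t_new = t + h;
        // spike detection on the soma voltage
        if (ynew[0] >= spike_threshold && y[0] < spike_threshold &&
            t_new >= last_spike + lockout) {
          const double frac = (spike_threshold - y[0]) / (ynew[0] - y[0]);
          const double ts = t + frac * h;
          if (ts >= last_spike + lockout) { spikes.push_back(ts); last_spike = ts; }
        }
        // b time-average accumulation (trapezoid) beyond the transient
        if (t_new > b_t0) {
          const double lo = std::max(t, b_t0);
          const double w = t_new - lo;
          // linear interpolation of b over the step
          const double bl = y[b_idx] + (lo - t) / h * (ynew[b_idx] - y[b_idx]);
          b_int += 0.5 * (bl + ynew[b_idx]) * w;
        }
        if (recording) {
          // cubic Hermite dense output from the step endpoints and slopes
          while (next_rec <= t_new + 1e-12 && next_rec <= duration) {
            const double th = (next_rec - t) / h;
            std::vector<double> yr(dim);
            for (int i = 0; i < dim; ++i) {
              const double dy = ynew[i] - y[i];
              yr[i] = y[i] + th * dy +
                th * (th - 1.0) * ((1.0 - 2.0 * th) * dy +
                                   (th - 1.0) * h * k1[i] + th * h * k7[i]);
            }
            rec_t.push_back(next_rec); rec_y.push_back(yr);
            next_rec += record_dt;
          }
        }
        y.swap(ynew);
        k1.swap(k7);  // FSAL
        t = t_new;
        const double fac = std::min(5.0, std::max(0.2,
            0.9 * std::pow(err > 1e-12 ? 1.0 / err : 1e12, 0.2)));
        h = std::min(h * fac, t_seg_end - t > 0 ? t_seg_end - t : h * fac);
        if (h <= 0) h = 1e-6;
      } else {
        ++n_reject;
        h *= std::max(0.2, 0.9 * std::pow(1.0 / err, 0.2));
      }
    }
    t = t_seg_end;
  }

  const double b_mean = duration > transient ? b_int / (duration - transient)
                                             : NA_REAL;
  List out = List::create(
    _["spike_times"] = wrap(spikes),
    _["final_state"] = wrap(y),
    _["b_mean"] = b_mean,
    _["n_steps"] = (double)n_steps,
    _["n_reject"] = (double)n_reject);
  if (recording) {
    const int nt = rec_t.size();
    NumericMatrix Y(nt, dim);
    for (int r = 0; r < nt; ++r)
      for (int i = 0; i < dim; ++i) Y(r, i) = rec_y[r][i];
    out["time"] = wrap(rec_t);
    out["states"] = Y;
  }
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".sim_point_cpp")]]
List sim_point_cpp(List params, NumericVector tE, NumericVector tI,
                   NumericVector y0, double duration, double transient,
                   double spike_threshold, double lockout,
                   double abstol, double reltol, double record_dt) {
  Params p = read_params(params);
  return integrate_model(p, false, tE, tI, y0, duration, transient,
                         spike_threshold, lockout, abstol, reltol, record_dt);
}

// [[Rcpp::export(name = ".sim_cable_cpp")]]
List sim_cable_cpp(List params, NumericVector tE, NumericVector tI,
                   NumericVector y0, double duration, double transient,
                   double spike_threshold, double lockout,
                   double abstol, double reltol, double record_dt) {
  Params p = read_params(params);
  return integrate_model(p, true, tE, tI, y0, duration, transient,
                         spike_threshold, lockout, abstol, reltol, record_dt);
}

// Scalar inactivation dynamics driven by the quasi-steady single-input
// voltage: b' = phi_b (b_inf(Vq(s(t))) - b) / tau_b with
// Vq(s) = (g_L V_L + g s V_rev) / (g_L + g s).  Classical RK4 with fixed
// step; the event gate is evaluated in closed form.  Returns the time
// average of b over [transient, duration] and the final value.
// [[Rcpp::export(name = ".sim_b_quasi_cpp")]]
List sim_b_quasi_cpp(List params, NumericVector events, double beta,
                     double g_syn, double V_rev, double b0,
                     double duration, double transient, double dt) {
  Params p = read_params(params);
  const int nev = events.size();
  int iev = 0;
  double s = 0.0, t_gate = 0.0;
  double b = b0, t = 0.0;
  double b_int = 0.0;
  auto vq = [&](double ss) {
    return (p.g_L * p.V_L + g_syn * ss * V_rev) / (p.g_L + g_syn * ss);
  };
  auto db = [&](double tt, double bb) {
    const double ss = s * std::exp(-beta * (tt - t_gate));
    return p.phi_b * (b_inf(p, vq(ss)) - bb) / p.tau_b;
  };
  while (t < duration - 1e-12) {
    while (iev < nev && events[iev] <= t + 1e-12) {
      s = 1.0; t_gate = events[iev]; ++iev;
    }
    double t_end = duration;
    if (iev < nev) t_end = std::min(t_end, events[iev]);
    while (t < t_end - 1e-12) {
      const double h = std::min(dt, t_end - t);
      const double q1 = db(t, b);
      const double q2 = db(t + h / 2, b + h / 2 * q1);
      const double q3 = db(t + h / 2, b + h / 2 * q2);
      const double q4 = db(t + h, b + h * q3);
      const double bn = b + h / 6 * (q1 + 2 * q2 + 2 * q3 + q4);
      if (t + h > transient) {
        const double lo = std::max(t, transient);
        b_int += 0.5 * (b + bn) * (t + h - lo);
      }
      b = bn; t += h;
    }
    t = t_end;
  }
  return List::create(
    _["b_mean"] = b_int / (duration - transient),
    _["b_final"] = b);
}
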