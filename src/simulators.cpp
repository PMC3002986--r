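#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// All kernels draw from R's RNG (RNGScope via Rcpp attributes), so a single
// set.seed() in the calling R wrapper makes every run reproducible.

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// Exact Gillespie simulation of N two-state channels with a piecewise-constant
// activation schedule p_inf(t).  Opening propensity (N-n)*p/tau_a, closing
// n*(1-p)/tau_a.  Proposed waiting times are capped at the next schedule
// breakpoint and redrawn there (exact for piecewise-constant rates because the
// exponential distribution is memoryless).
// [[Rcpp::export]]
List cpp_gillespie_two_state(int N, double tau_a, NumericVector sched_t,
                             NumericVector sched_p, int n0, double t_end) {
  std::vector<double> times;
  std::vector<int> nopen;
  times.push_back(0.0);
  nopen.push_back(n0);
  double t = 0.0;
  int n = n0, seg = 0;
  const int nseg = sched_t.size();
  while (seg + 1 < nseg && sched_t[seg + 1] <= t) ++seg;
  while (t < t_end) {
    const double p = sched_p[seg];
    double t_break = (seg + 1 < nseg) ? sched_t[seg + 1] : t_end;
    if (t_break > t_end) t_break = t_end;
    const double r_open = (N - n) * p / tau_a;
    const double r_close = n * (1.0 - p) / tau_a;
    const double rt = r_open + r_close;
    double t_next = t_break;
    if (rt > 0.0) {
      const double w = R::exp_rand() / rt;
      if (t + w < t_break) t_next = t + w;
    }
    if (t_next >= t_break) {
      t = t_break;
      while (seg + 1 < nseg && sched_t[seg + 1] <= t) ++seg;
      continue;
    }
    t = t_next;
    if (R::unif_rand() * rt < r_open) ++n; else --n;
    times.push_back(t);
    nopen.push_back(n);
  }
  return List::create(_["times"] = times, _["n_open"] = nopen);
}

// ---------------------------------------------------------------------------
// helpers for the deterministic adaptation filter  tau_a * abar' = f - abar
// with f constant on the integration segment
static inline double abar_end(double a0, double f, double h, double tau) {
  return f + (a0 - f) * std::exp(-h / tau);
}
static inline double abar_int(double a0, double f, double h, double tau) {
  return f * h + (a0 - f) * tau * (-std::expm1(-h / tau));
}

// exact conditional update of an OU fluctuation eta (variance s2, correlation
// time tau) together with its time integral over a step h
struct OUStep {
  double eh, bh, a11, a21, a22, tau;
  void set(double s2, double tau_, double h) {
    tau = tau_;
    const double x = h / tau;
    eh = std::exp(-x);
    bh = -std::expm1(-x);
    const double v1 = s2 * (1.0 - eh * eh);
    double G = 2.0 * x - 3.0 + 4.0 * eh - eh * eh;   // Var integral / (s2*tau^2)
    if (x < 0.02)
      G = (2.0 / 3.0) * x * x * x * (1.0 - 0.75 * x + 0.35 * x * x);
    const double v2 = s2 * tau * tau * G;
    const double c12 = s2 * tau * bh * bh;
    a11 = std::sqrt(v1);
    a21 = (a11 > 0.0) ? c12 / a11 : 0.0;
    double rest = v2 - a21 * a21;
    a22 = (rest > 0.0) ? std::sqrt(rest) : 0.0;
  }
  // advances eta in place, returns the integral of eta over the step
  double advance(double &eta) {
    const double z1 = R::norm_rand(), z2 = R::norm_rand();
    const double I = eta * tau * bh + a21 * z1 + a22 * z2;
    eta = eta * eh + a11 * z1;
    return I;
  }
};

// ---------------------------------------------------------------------------
// Adaptive perfect integrate-and-fire neuron.
//   dv/dt = mu(t) - Delta * a(t) + sqrt(2 D) xi(t),  spike at theta, reset 0
// a(t) is the open fraction: exact channel counts (mode 1), the deterministic
// filter abar (mode 0), or abar plus an OU fluctuation eta (mode 2, diffusion
// approximation).  Spiking sets the channel activation p_inf to 1 for a pulse
// of length delta_pulse (a new spike restarts the pulse clock); between pulses
// p_inf = p0 (subthreshold activation).  mu(t) = mu + step_dmu for t >= step_t.
//
// mode 1, D = 0: fully event-driven and statistically exact.
// mode 1, D > 0: event-driven channels, white noise added on substeps <= dt,
//                threshold crossing located by linear interpolation.
// mode 0/2:      steps of dt cut at pulse boundaries; abar updated exactly;
//                eta and its integral updated by the exact conditional-Gaussian
//                pair; white noise Euler-Maruyama; crossing by interpolation
//                (D = 0, mode 0: analytic crossing via safeguarded Newton).
// [[Rcpp::export]]
List cpp_sim_pif(double mu, double Delta, double tau_a, double delta_pulse,
                 double p0, double theta, double D, double dt, double t_end,
                 double N, int adapt_mode, double sigma2_eta,
                 double a_init, int n_init, double eta_init, double v_init,
                 bool keep_traj, double step_t, double step_dmu) {
  std::vector<double> spikes;
  std::vector<double> tr_t;
  std::vector<double> tr_a;
  int overlaps = 0;
  double t = 0.0, v = v_init;
  double pulse_end = -1.0;
  const bool has_step = (step_t >= 0.0);
  spikes.reserve(1024);

  if (adapt_mode == 1) {
    // ----- channel model -----
    int n = n_init;
    const int Ni = (int)N;
    const double cap = (D > 0.0) ? dt : INF;
    if (keep_traj) { tr_t.push_back(0.0); tr_a.push_back(n); }
    while (t < t_end) {
      const double mu_c = mu + ((has_step && t >= step_t) ? step_dmu : 0.0);
      const bool in_pulse = (t < pulse_end);
      const double p = in_pulse ? 1.0 : p0;
      double t_break = t_end;
      if (in_pulse && pulse_end < t_break) t_break = pulse_end;
      if (has_step && t < step_t && step_t < t_break) t_break = step_t;
      if (t + cap < t_break) t_break = t + cap;
      const double r_open = (Ni - n) * p / tau_a;
      const double r_close = n * (1.0 - p) / tau_a;
      const double rt = r_open + r_close;
      double t_chan = INF;
      if (rt > 0.0) t_chan = t + R::exp_rand() / rt;
      double t_next = std::min(t_chan, t_break);
      const double drift = mu_c - Delta * n / N;
      double h = t_next - t;
      if (D > 0.0) {
        // stochastic substep
        const double dW = std::sqrt(2.0 * D * h) * R::norm_rand();
        const double v_new = v + drift * h + dW;
        if (v_new >= theta) {
          const double frac = (v_new > v) ? (theta - v) / (v_new - v) : 0.0;
          const double t_sp = t + frac * h;
          spikes.push_back(t_sp);
          if (t_sp < pulse_end) ++overlaps;
          pulse_end = t_sp + delta_pulse;
          v = 0.0;
          t = t_sp;         // rates change here; exponential redraw is exact
          continue;
        }
        v = v_new;
      } else {
        // deterministic drift: exact crossing time
        if (drift > 0.0) {
          const double t_sp = t + (theta - v) / drift;
          if (t_sp <= t_next) {
            spikes.push_back(t_sp);
            if (t_sp < pulse_end) ++overlaps;
            pulse_end = t_sp + delta_pulse;
            v = 0.0;
            t = t_sp;
            continue;
          }
        }
        v += drift * h;
      }
      t = t_next;
      if (t_chan <= t_break) {
        if (R::unif_rand() * rt < r_open) ++n; else --n;
        if (keep_traj) { tr_t.push_back(t); tr_a.push_back(n); }
      }
    }
    return List::create(_["spikes"] = spikes, _["overlaps"] = overlaps,
                        _["traj_t"] = tr_t, _["traj_n"] = tr_a);
  }

  // ----- mode 0 (deterministic adaptation) / mode 2 (diffusion) -----
  double abar = a_init, eta = eta_init;
  OUStep ou;
  double ou_h = -1.0;
  const bool exact_det = (adapt_mode == 0 && D <= 0.0);
  while (t < t_end) {
    const double mu_c = mu + ((has_step && t >= step_t) ? step_dmu : 0.0);
    const bool in_pulse = (t < pulse_end);
    const double f = in_pulse ? 1.0 : p0;
    double t_break = t_end;
    if (in_pulse && pulse_end < t_break) t_break = pulse_end;
    if (has_step && t < step_t && step_t < t_break) t_break = step_t;
    double h = std::min(dt, t_break - t);
    if (h <= 0.0) { t = t_break; continue; }

    if (exact_det) {
      // analytic voltage on the whole segment up to t_break
      h = t_break - t;
      const double a0 = abar;
      // V(s) = v + mu_c s - Delta * abar_int(a0, f, s, tau_a); find first s
      // with V(s) = theta on (0, h], if any.  V' is monotone in s.
      double s_hit = -1.0;
      const double Vend = v + mu_c * h - Delta * abar_int(a0, f, h, tau_a);
      double s_hi = -1.0;
      if (Vend >= theta) s_hi = h;
      else {
        // V has at most one interior maximum (where drive = 0)
        const double target = mu_c / Delta;
        if (Delta > 0.0 && (a0 - f) != 0.0) {
          const double ratio = (target - f) / (a0 - f);
          if (ratio > 0.0 && ratio < 1.0) {
            const double s_star = -tau_a * std::log(ratio);
            if (s_star > 0.0 && s_star < h) {
              const double Vstar =
                  v + mu_c * s_star - Delta * abar_int(a0, f, s_star, tau_a);
              if (Vstar >= theta) s_hi = s_star;
            }
          }
        }
      }
      if (s_hi > 0.0) {
        double lo = 0.0, hi = s_hi;
        for (int it = 0; it < 200; ++it) {
          const double mid = 0.5 * (lo + hi);
          const double Vm =
              v + mu_c * mid - Delta * abar_int(a0, f, mid, tau_a);
          if (Vm >= theta) hi = mid; else lo = mid;
          if (hi - lo < 1e-14 * std::max(1.0, hi)) break;
        }
        s_hit = 0.5 * (lo + hi);
      }
      if (s_hit > 0.0) {
        const double t_sp = t + s_hit;
        spikes.push_back(t_sp);
        if (t_sp < pulse_end) ++overlaps;
        abar = abar_end(a0, f, s_hit, tau_a);
        pulse_end = t_sp + delta_pulse;
        v = 0.0;
        t = t_sp;
      } else {
        abar = abar_end(a0, f, h, tau_a);
        v = Vend;
        t = t_break;
      }
      continue;
    }

    const double a0 = abar;
    double int_a = abar_int(a0, f, h, tau_a);
    abar = abar_end(a0, f, h, tau_a);
    double int_eta = 0.0;
    if (adapt_mode == 2 && sigma2_eta > 0.0) {
      if (h != ou_h) { ou.set(sigma2_eta, tau_a, h); ou_h = h; }
      int_eta = ou.advance(eta);
    }
    double dv = mu_c * h - Delta * (int_a + int_eta);
    if (D > 0.0) dv += std::sqrt(2.0 * D * h) * R::norm_rand();
    double v_new = v + dv;
    if (v_new >= theta) {
      const double frac = (dv > 0.0) ? (theta - v) / dv : 0.0;
      const double t_sp = t + frac * h;
      spikes.push_back(t_sp);
      if (t_sp < pulse_end) ++overlaps;
      // correct abar and v for the pulse occupying [t_sp, t+h]
      const double tail = h - frac * h;
      const double a_sp = abar_end(a0, f, frac * h, tau_a);
      const double abar_corr = abar_end(a_sp, 1.0, tail, tau_a);
      const double int_corr =
          abar_int(a0, f, frac * h, tau_a) + abar_int(a_sp, 1.0, tail, tau_a);
      v_new -= theta + Delta * (int_corr - int_a);
      abar = abar_corr;
      pulse_end = t_sp + delta_pulse;
      if (v_new >= theta) v_new = theta * 0.999999;  // pathological guard
    }
    v = v_new;
    t += h;
  }
  return List::create(_["spikes"] = spikes, _["overlaps"] = overlaps,
                      _["traj_t"] = tr_t, _["traj_n"] = tr_a);
}

// ---------------------------------------------------------------------------
// PIF neuron driven by a constant drive mu_eff and an OU colored noise
// (variance sigma2_eff, correlation time tau_eff); no adaptation feedback.
// Because the drift never depends on v, the reset dynamics is equivalent to
// unwrapped integration with spikes at every multiple of theta; the OU pair
// update is exact and crossings are located by linear interpolation.
// [[Rcpp::export]]
NumericVector cpp_sim_pif_colored(double mu_eff, double theta, double tau_eff,
                                  double sigma2_eff, double eta_init,
                                  double dt, double t_end) {
  std::vector<double> spikes;
  spikes.reserve(1024);
  if (sigma2_eff <= 0.0) {
    const double T = theta / mu_eff;
    for (double ts = T; ts <= t_end; ts += T) spikes.push_back(ts);
    return NumericVector(spikes.begin(), spikes.end());
  }
  OUStep ou;
  ou.set(sigma2_eff, tau_eff, dt);
  double eta = eta_init, V = 0.0, t = 0.0;
  double next_level = theta;
  const long nsteps = (long)std::ceil(t_end / dt);
  for (long k = 0; k < nsteps; ++k) {
    const double dV = mu_eff * dt + ou.advance(eta);
    const double V_new = V + dV;
    while (V_new >= next_level && dV > 0.0) {
      const double frac = (next_level - V) / dV;
      spikes.push_back(t + frac * dt);
      next_level += theta;
    }
    V = V_new;
    t += dt;
  }
  return NumericVector(spikes.begin(), spikes.end());
}

// ---------------------------------------------------------------------------
// Traub-Miles model with M-type adaptation current (Ermentrout variant)
static inline double vtrap(double x, double y) {
  // x / (1 - exp(-x/y)), stable near x = 0
  const double r = x / y;
  if (std::fabs(r) < 1e-6) return y * (1.0 + 0.5 * r);
  return x / (-std::expm1(-r));
}
static inline double tm_am(double V) { return 0.32 * vtrap(V + 54.0, 4.0); }
static inline double tm_bm(double V) { return 0.28 * vtrap(-(V + 27.0), 5.0); }
static inline double tm_ah(double V) { return 0.128 * std::exp(-(V + 50.0) / 18.0); }
static inline double tm_bh(double V) { return 4.0 / (1.0 + std::exp(-(V + 27.0) / 5.0)); }
static inline double tm_an(double V) { return 0.032 * vtrap(V + 52.0, 5.0); }
static inline double tm_bn(double V) { return 0.5 * std::exp(-(V + 57.0) / 40.0); }
static inline double tm_winf(double V) { return 1.0 / (1.0 + std::exp(-(V + 35.0) / 10.0)); }
static inline double tm_tauw(double V, double scale) {
  return scale * 100.0 /
         (3.3 * std::exp((V + 35.0) / 20.0) + std::exp(-(V + 35.0) / 20.0));
}

// steady states and time constants of all gating variables at voltage V
// [[Rcpp::export]]
NumericVector cpp_tm_gating(double V, double tauw_scale) {
  const double am = tm_am(V), bm = tm_bm(V);
  const double ah = tm_ah(V), bh = tm_bh(V);
  const double an = tm_an(V), bn = tm_bn(V);
  return NumericVector::create(
      _["m_inf"] = am / (am + bm), _["tau_m"] = 1.0 / (am + bm),
      _["h_inf"] = ah / (ah + bh), _["tau_h"] = 1.0 / (ah + bh),
      _["n_inf"] = an / (an + bn), _["tau_n"] = 1.0 / (an + bn),
      _["w_inf"] = tm_winf(V), _["tau_w"] = tm_tauw(V, tauw_scale));
}

// [[Rcpp::export]]
List cpp_sim_tm(double C, double gNa, double ENa, double gK, double EK,
                double gL, double EL, double gM, double I, double D,
                double tauw_scale, double dt, double t_end, bool stoch_m,
                int N, double refresh_cap, int store_every,
                double detect_threshold, double refractory,
                double V0, double w0) {
  std::vector<double> spikes, tr_t, tr_v, tr_w;
  double V = V0;
  double m = 0.0, h = 1.0, n = 0.0, w = w0;
  { // start gating at steady state for V0
    const double am = tm_am(V), bm = tm_bm(V), ah = tm_ah(V), bh = tm_bh(V),
                 an = tm_an(V), bn = tm_bn(V);
    m = am / (am + bm); h = ah / (ah + bh); n = an / (an + bn);
  }
  int nop = stoch_m ? (int)std::lround(w0 * N) : 0;
  const long nsteps = (long)std::ceil(t_end / dt);
  const double sqn = std::sqrt(2.0 * D * dt) / C;
  double t = 0.0, last_spike = -1e18, V_prev = V;
  const double refresh = std::min(dt, refresh_cap);
  for (long k = 0; k < nsteps; ++k) {
    const double am = tm_am(V), bm = tm_bm(V), ah = tm_ah(V), bh = tm_bh(V),
                 an = tm_an(V), bn = tm_bn(V);
    // exponential-Euler gating updates (explicit, unconditionally stable)
    const double minf = am / (am + bm), taum = 1.0 / (am + bm);
    const double hinf = ah / (ah + bh), tauh = 1.0 / (ah + bh);
    const double ninf = an / (an + bn), taun = 1.0 / (an + bn);
    m = minf + (m - minf) * std::exp(-dt / taum);
    h = hinf + (h - hinf) * std::exp(-dt / tauh);
    n = ninf + (n - ninf) * std::exp(-dt / taun);
    double a_frac;
    if (stoch_m) {
      // Gillespie channel gating with rates frozen over at most `refresh`
      const double winf = tm_winf(V), tauw = tm_tauw(V, tauw_scale);
      const double ro1 = winf / tauw, rc1 = (1.0 - winf) / tauw;
      double tl = 0.0;
      while (tl < dt) {
        const double seg = std::min(refresh, dt - tl);
        double tt = 0.0;
        while (true) {
          const double ro = (N - nop) * ro1, rc = nop * rc1, rt = ro + rc;
          if (rt <= 0.0) break;
          tt += R::exp_rand() / rt;
          if (tt > seg) break;
          if (R::unif_rand() * rt < ro) ++nop; else --nop;
        }
        tl += seg;
      }
      a_frac = (double)nop / N;
    } else {
      const double winf = tm_winf(V), tauw = tm_tauw(V, tauw_scale);
      w = winf + (w - winf) * std::exp(-dt / tauw);
      a_frac = w;
    }
    const double Iion = gNa * m * m * m * h * (V - ENa) + gK * n * n * n * n * (V - EK) +
                        gL * (V - EL) + gM * a_frac * (V - EK);
    double dV = (I - Iion) / C * dt;
    if (D > 0.0) dV += sqn * R::norm_rand();
    V_prev = V;
    V += dV;
    if (!std::isfinite(V))
      stop("Traub-Miles integration diverged (voltage not finite); reduce the step size dt = %f ms", dt);
    t += dt;
    if (V_prev < detect_threshold && V >= detect_threshold &&
        t - last_spike > refractory) {
      const double frac = (detect_threshold - V_prev) / (V - V_prev);
      last_spike = t - dt + frac * dt;
      spikes.push_back(last_spike);
    }
    if (store_every > 0 && (k % store_every) == 0) {
      tr_t.push_back(t);
      tr_v.push_back(V);
      tr_w.push_back(stoch_m ? (double)nop : w);
    }
  }
  return List::create(_["spikes"] = spikes, _["trace_t"] = tr_t,
                      _["trace_v"] = tr_v, _["trace_w"] = tr_w);
}
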