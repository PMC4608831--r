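#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Steady-state gate and time-constant expressions of the TS neuron model.
// Removable singularities of alpha_m / alpha_n at V = -40.7 mV are replaced
// by their analytic limits.
static inline double alpha_m(double V) {
  double x = V + 40.7;
  if (std::fabs(x) < 1e-7) return 1.0;
  return 0.1 * x / (1.0 - std::exp(-0.1 * x));
}
static inline double beta_m(double V) {
  return 4.0 * std::exp(-0.05 * (V + 49.7));
}
static inline double alpha_n(double V) {
  double x = V + 40.7;
  if (std::fabs(x) < 1e-7) return 0.1;
  return 0.01 * x / (1.0 - std::exp(-0.1 * x));
}
static inline double beta_n(double V) {
  return 0.125 * std::exp(-0.0125 * (V + 50.7));
}
static inline double m_inf(double V) {
  double a = alpha_m(V);
  return a / (a + beta_m(V));
}
static inline double n_inf_f(double V) {
  double a = alpha_n(V);
  return a / (a + beta_n(V));
}
static inline double tau_n_f(double V, double num) {
  return num / (alpha_n(V) + beta_n(V));
}
static inline double h_inf_f(double V) {
  return 1.0 / (1.0 + std::exp(0.151 * (V + 73.0)));
}
static inline double tau_h_f(double V) {
  return std::exp(0.033 * (V + 75.0)) /
         (0.011 * (1.0 + std::exp(0.083 * (V + 75.0))));
}
static inline double s_inf_f(double V) {
  return 1.0 / (1.0 + std::exp(-(V + 63.0) / 7.8));
}
// Two readings of the typeset T-current inactivation steady state; 0 =
// "literal" 1/(0.5 + 0.25 + exp((V+82)/6.3)), 1 = "product"
// 1/(0.5 + 0.25 exp((V+82)/6.3)).
static inline double eta_inf_f(double V, int parse) {
  double e = std::exp((V + 82.0) / 6.3);
  if (parse == 1) return 1.0 / (0.5 + 0.25 * e);
  return 1.0 / (0.75 + e);
}

// Euler-Maruyama integration of the stochastic TS neuron driven by ON/OFF
// synaptic conductance series sampled at g_bin_ms. par layout:
//  0 C, 1 gNa, 2 gK, 3 gleak, 4 gh, 5 gT, 6 ENa, 7 EK, 8 Eleak, 9 Eh,
// 10 ECa, 11 Ibias, 12 sigma_noise, 13 noise_sd, 14 Phi, 15 tau_eta,
// 16 dt, 17 eta_parse (0/1), 18 tau_n_num
// syn layout: 0 sigma_B, 1 W_s, 2 g_max, 3 E_syn
// During the first n_burn steps the conductances are held at their first
// sample so the state settles before the stimulus proper.
// [[Rcpp::export]]
List integrate_ts_cpp(NumericVector par, NumericVector g_on,
                      NumericVector g_off, double g_bin_ms,
                      NumericVector syn, double t_end_ms, int n_burn,
                      bool record_v) {
  const double C = par[0], gNa = par[1], gK = par[2], gleak = par[3],
               gh = par[4], gT = par[5], ENa = par[6], EK = par[7],
               Eleak = par[8], Eh = par[9], ECa = par[10], Ibias = par[11],
               sigma_noise = par[12], noise_sd = par[13], Phi = par[14],
               tau_eta = par[15], dt = par[16];
  const int eta_parse = (int)par[17];
  const double tau_n_num = par[18];
  const double sigma_B = syn[0], W_s = syn[1], E_syn = syn[3];
  const int n_steps = (int)std::llround(t_end_ms / dt);
  const int ng = g_on.size();
  const double noise_amp = sigma_noise * noise_sd * std::sqrt(dt) / C;

  double V = Eleak;
  double eta = eta_inf_f(V, eta_parse);
  double h = h_inf_f(V);
  double n = n_inf_f(V);

  NumericVector Vout(record_v ? n_steps + 1 : 1);
  if (record_v) Vout[0] = V;
  int diverged_at = -1;

  for (int i = -n_burn; i < n_steps; ++i) {
    double gon = 0.0, goff = 0.0;
    if (ng > 0) {
      if (i <= 0) {
        gon = g_on[0];
        goff = g_off[0];
      } else {
        // linear interpolation of the conductance series at t = i*dt
        double pos = i * dt / g_bin_ms;
        int k = (int)pos;
        if (k >= ng - 1) {
          gon = g_on[ng - 1];
          goff = g_off[ng - 1];
        } else {
          double w = pos - k;
          gon = (1.0 - w) * g_on[k] + w * g_on[k + 1];
          goff = (1.0 - w) * g_off[k] + w * g_off[k + 1];
        }
      }
    }
    double mi = m_inf(V);
    double INa = -gNa * mi * mi * mi * (0.85 - n) * (V - ENa);
    double IK = -gK * n * n * n * n * (V - EK);
    double Ih = -gh * h * (V - Eh);
    double si = s_inf_f(V);
    double IT = -gT * si * si * si * eta * (V - ECa);
    double Il = -gleak * (V - Eleak);
    double Isyn = -2.0 * W_s * (sigma_B * gon + (1.0 - sigma_B) * goff) *
                  (V - E_syn);
    double dV = dt * (INa + IK + Ih + IT + Il + Isyn + Ibias) / C;
    if (sigma_noise > 0.0) dV += noise_amp * norm_rand();

    eta += dt * Phi * (eta_inf_f(V, eta_parse) - eta) / tau_eta;
    h += dt * (h_inf_f(V) - h) / tau_h_f(V);
    n += dt * (n_inf_f(V) - n) / tau_n_f(V, tau_n_num);
    V += dV;

    if (!std::isfinite(V) || !std::isfinite(eta) || !std::isfinite(h) ||
        !std::isfinite(n)) {
      diverged_at = i;
      break;
    }
    if (record_v && i >= 0) Vout[i + 1] = V;
  }

  return List::create(Named("V") = Vout, Named("dt") = dt,
                      Named("diverged_at") = diverged_at,
                      Named("final_state") = NumericVector::create(V, eta, h, n));
}

// Exact Victor-Purpura distance by dynamic programming: insert/delete cost 1,
// shift cost q_per_s * |dt| with spike times in ms.
// [[Rcpp::export]]
double vpd_cpp(NumericVector a, NumericVector b, double q_per_s) {
  const int na = a.size(), nb = b.size();
  const double q = q_per_s / 1000.0;  // cost per ms
  if (na == 0) return nb;
  if (nb == 0) return na;
  std::vector<double> prev(nb + 1), cur(nb + 1);
  for (int j = 0; j <= nb; ++j) prev[j] = j;
  for (int i = 1; i <= na; ++i) {
    cur[0] = i;
    for (int j = 1; j <= nb; ++j) {
      double shift = prev[j - 1] + q * std::fabs(a[i - 1] - b[j - 1]);
      double del = prev[j] + 1.0;
      double ins = cur[j - 1] + 1.0;
      cur[j] = std::min(shift, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[nb];
}

// Mean pairwise Victor-Purpura distance over all unordered pairs of a pooled
// list of spike trains.
// [[Rcpp::export]]
double vpd_avg_cpp(List trains, double q_per_s) {
  const int n = trains.size();
  double total = 0.0;
  long m = 0;
  for (int i = 0; i < n; ++i) {
    NumericVector a = trains[i];
    for (int j = i + 1; j < n; ++j) {
      NumericVector b = trains[j];
      total += vpd_cpp(a, b, q_per_s);
      ++m;
    }
  }
  return total / (double)m;
}
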