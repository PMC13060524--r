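#include <Rcpp.h>
using namespace Rcpp;

// Explicit Euler-Maruyama integrator for the coupled optical-thermal-servo
// dynamics of a PDH-locked cavity. The optical field is adiabatic (photon
// lifetime ~ns << dt), so intracavity power follows the instantaneous
// Lorentzian. State: servo low-pass output u, integrator iota, lock detuning
// (servo actuator), thermal offset Theta, OU detuning noise xi.
//
// delta = delta_lock + delta_th + xi + delta_ext
// T     = 1/(1+x^2),  e = x/(1+x^2)^2,  x = 2 delta / kappa
// du    = 2 pi f_lp (e - e_set - u) dt        (servo input low-pass)
// diota = u dt                                 (integrator)
// delta_lock = -k_act (g_p u + g_i iota)       (negative feedback)
// dTheta = (-Theta/tau_th + c_abs P_in T) dt   (single thermal pole)
// delta_th = k_T (Theta - Theta_op)            (engaged after settling)
// dxi = -xi/tau_n dt + sigma sqrt(2 dt / tau_n) N(0,1)
//
// Theta_op is captured at the end of the settling window so the thermal
// feedback engages with zero offset; uses R's RNG (seed with set.seed()).

// [[Rcpp::export]]
List sim_core(NumericVector delta_ext, double dt, int decim,
              double kappa,
              double g_p, double g_i, double e_set, double f_lp, double k_act,
              double tau_th, double c_abs, double k_T, double P_in,
              double noise_sigma, double noise_tau, double det_sigma,
              double settle_time,
              double lockbreak_mult, double lockbreak_dur) {
  const int n = delta_ext.size();
  const int n_out = n / decim;
  NumericVector trans(n_out);
  NumericVector det_out(n_out);

  double u = 0.0, iota = 0.0, delta_lock = 0.0;
  double Theta = 0.0, Theta_op = 0.0, xi = 0.0;
  bool engaged = false;
  const int settle_steps = (int)(settle_time / dt);

  const double a_lp = 2.0 * M_PI * f_lp * dt;
  const double ou_decay = dt / noise_tau;
  const double ou_kick = noise_sigma * std::sqrt(2.0 * dt / noise_tau);

  bool lock_break = false, diverged = false;
  double diverge_time = NA_REAL;
  int over_count = 0;
  const int over_limit = (int)(lockbreak_dur / dt);

  double acc_T = 0.0, acc_d = 0.0;
  int acc_n = 0, i_out = 0;

  for (int i = 0; i < n; ++i) {
    double delta_th = engaged ? k_T * (Theta - Theta_op) : 0.0;
    double delta = delta_lock + delta_th + xi + delta_ext[i];
    double x = 2.0 * delta / kappa;
    double den = 1.0 + x * x;
    double T = 1.0 / den;
    double e = x / (den * den);

    u += a_lp * (e - e_set - u);
    iota += u * dt;
    delta_lock = -k_act * (g_p * u + g_i * iota);

    Theta += (-Theta / tau_th + c_abs * P_in * T) * dt;
    if (!engaged && i >= settle_steps) { Theta_op = Theta; engaged = true; }

    xi += -xi * ou_decay + ou_kick * norm_rand();

    if (!R_finite(delta) || !R_finite(Theta) || !R_finite(iota)) {
      diverged = true;
      diverge_time = i * dt;
      break;
    }
    if (std::fabs(delta) > lockbreak_mult * kappa) {
      if (++over_count > over_limit) lock_break = true;
    } else {
      over_count = 0;
    }

    acc_T += T;
    acc_d += delta;
    if (++acc_n == decim) {
      double v = acc_T / decim + det_sigma * norm_rand();
      // detector range clamp: normalized transmission with noise margin
      trans[i_out] = std::min(1.05, std::max(-0.05, v));
      det_out[i_out] = acc_d / decim;
      ++i_out;
      acc_T = 0.0; acc_d = 0.0; acc_n = 0;
    }
  }

  return List::create(
    _["transmission"] = trans,
    _["detuning"] = det_out,
    _["n_out"] = i_out,
    _["lock_break"] = lock_break,
    _["diverged"] = diverged,
    _["diverge_time"] = diverge_time,
    _["theta_op"] = Theta_op);
}
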