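#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of the three-population rate model with
// adaptation.  Noise samples (unit-variance OU states) are generated on the
// R side and passed in as a (n_steps + 1) x 3 matrix; row k is the noise
// state at time k * dt.  The transfer nonlinearity is the rectified-linear
// map g * [x - theta]_+ and the noise enters inside its argument.
//
// par must hold: tau_E, tau_I, tau_A, tau_a (ms), g_E, g_I, g_A (Hz per
// input unit), theta_E, theta_I, theta_A, sigma, beta (s), and J as a 3x3
// matrix with rows/cols ordered E, I, A (J[X, Y] = strength Y -> X, in s).
//
// Returns a (n_rec x 8) matrix: t_ms, r_E, r_I, r_A, a, xi_E, xi_I, xi_A.

// [[Rcpp::export]]
NumericMatrix rate_core(NumericVector init, NumericMatrix xi, List par,
                        double dt, int record_every) {
  const int n_steps = xi.nrow() - 1;
  const double tau_E = par["tau_E"], tau_I = par["tau_I"],
               tau_A = par["tau_A"], tau_a = par["tau_a"];
  const double g_E = par["g_E"], g_I = par["g_I"], g_A = par["g_A"];
  const double th_E = par["theta_E"], th_I = par["theta_I"],
               th_A = par["theta_A"];
  const double sigma = par["sigma"], beta = par["beta"];
  NumericMatrix J = par["J"];

  double rE = init[0], rI = init[1], rA = init[2], a = init[3];

  const int n_rec = n_steps / record_every + 1;
  NumericMatrix out(n_rec, 8);
  int row = 0;
  out(0, 0) = 0.0; out(0, 1) = rE; out(0, 2) = rI; out(0, 3) = rA;
  out(0, 4) = a; out(0, 5) = xi(0, 0); out(0, 6) = xi(0, 1);
  out(0, 7) = xi(0, 2);
  ++row;

  for (int k = 0; k < n_steps; ++k) {
    const double I_E = J(0, 0) * rE + J(0, 1) * rI + J(0, 2) * rA;
    const double I_I = J(1, 0) * rE + J(1, 1) * rI + J(1, 2) * rA;
    const double I_A = J(2, 0) * rE + J(2, 1) * rI + J(2, 2) * rA;

    const double arg_E = I_E - a + sigma * xi(k, 0) - th_E;
    const double arg_I = I_I + sigma * xi(k, 1) - th_I;
    const double arg_A = I_A + sigma * xi(k, 2) - th_A;

    const double phi_E = arg_E > 0.0 ? g_E * arg_E : 0.0;
    const double phi_I = arg_I > 0.0 ? g_I * arg_I : 0.0;
    const double phi_A = arg_A > 0.0 ? g_A * arg_A : 0.0;

    const double a_new = a + dt / tau_a * (-a + beta * rE);
    rE += dt / tau_E * (-rE + phi_E);
    rI += dt / tau_I * (-rI + phi_I);
    rA += dt / tau_A * (-rA + phi_A);
    a = a_new;

    if (!R_FINITE(rE) || !R_FINITE(rI) || !R_FINITE(rA) || !R_FINITE(a))
      stop("numerical blow-up at t = %f ms", (k + 1) * dt);

    if ((k + 1) % record_every == 0) {
      out(row, 0) = (k + 1) * dt;
      out(row, 1) = rE; out(row, 2) = rI; out(row, 3) = rA; out(row, 4) = a;
      out(row, 5) = xi(k + 1, 0); out(row, 6) = xi(k + 1, 1);
      out(row, 7) = xi(k + 1, 2);
      ++row;
    }
  }
  return out;
}
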