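#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// --- self-contained RNG -------------------------------------------------
// xoshiro256++ seeded via splitmix64, plus a ziggurat normal sampler whose
// tables are built numerically at initialization (256 equal-area layers;
// the rightmost abscissa is found by bisection), so the construction is
// correct by definition rather than by transcribed constants.

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9E3779B97F4A7C15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xBF58476D1CE4E5B9ULL;
      t = (t ^ (t >> 27)) * 0x94D049BB133111EBULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {           // in [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
};

struct Ziggurat {
  static const int N = 256;
  double xz[N + 1], fz[N + 1], r, x0;

  static double f(double x) { return std::exp(-0.5 * x * x); }
  static double tail_area(double x) {
    return std::sqrt(M_PI / 2.0) * std::erfc(x / std::sqrt(2.0));
  }
  // residual of the equal-area layer recursion: with abscissae
  // xz[1] = r > xz[2] > ... > xz[N-1] built bottom-up, a valid r closes
  // the construction with the next ordinate reaching f(0) = 1 exactly.
  // Positive residual means r is too small (layers collapse early).
  static double closure(double r, double* xs = 0) {
    const double V = r * f(r) + tail_area(r);
    double x = r;
    if (xs) xs[1] = r;
    for (int i = 2; i <= N - 1; ++i) {
      const double fi = f(x) + V / x;
      if (fi >= 1.0) return (N - i) + fi - 1.0;   // collapsed early
      x = std::sqrt(-2.0 * std::log(fi));
      if (xs) xs[i] = x;
    }
    return f(x) + V / x - 1.0;
  }
  Ziggurat() {
    double lo = 2.0, hi = 4.0;
    for (int it = 0; it < 200; ++it) {
      const double mid = 0.5 * (lo + hi);
      if (closure(mid) > 0.0) lo = mid; else hi = mid;
    }
    r = 0.5 * (lo + hi);
    const double V = r * f(r) + tail_area(r);
    closure(r, xz);          // fills xz[1..N-1]
    xz[N] = 0.0;
    x0 = V / f(r);           // pseudo-width of the base layer
    xz[0] = x0;
    for (int i = 1; i <= N; ++i) fz[i] = f(xz[i]);
    fz[0] = f(r);
  }
  inline double draw(Xoshiro& rng) const {
    for (;;) {
      const uint64_t bits = rng.next();
      const int i = (int)(bits & 255);
      const double sign = (bits & 256) ? 1.0 : -1.0;
      const double u = ((bits >> 11) * 0x1.0p-53);
      const double x = u * xz[i];
      if (x < xz[i + 1]) return sign * x;
      if (i == 0) {                     // tail beyond r (Marsaglia)
        double xx, yy;
        do {
          xx = -std::log(rng.unif() + 1e-300) / r;
          yy = -std::log(rng.unif() + 1e-300);
        } while (2.0 * yy < xx * xx);
        return sign * (r + xx);
      }
      const double y = fz[i] + rng.unif() * (fz[i + 1] - fz[i]);
      if (y < f(x)) return sign * x;
    }
  }
};

const Ziggurat zigg;

}  // namespace

// Event-queue Euler simulator for the stochastic spiking network:
// leaky integrate-and-fire E/I neurons, integrate-and-release astrocytes,
// population synaptic variables (u_X, s_X), per-event transmission delays
// and an after-hyperpolarization (AHP) current on the excitatory cells.
//
// Conventions (documented in the R wrappers):
//  * threshold crossing is tested after the Euler update; reset is applied
//    the same step and the spike time is the end-of-step time;
//  * each spike/release event draws a delay ~ Uniform[d_min, d_max],
//    rounded to the nearest dt bin (a ring buffer per population);
//  * a matured event increments u_X by tau_bar_X / tau_r_X (the exact
//    integral of the printed delta impulse through the u equation);
//  * white-noise input realized as sigma_X * sqrt(dt / tau_X) * N(0,1);
//  * the V/G updates of a step read the s_X values from the start of the
//    step; u and s are then advanced (first-order splitting).
//
// state: V_E, V_I, G_A, I_a, u (3), s (3), q_E, q_I, q_A (ring buffers of
//        pending event counts per dt bin), head (3, 0-based), t_ms.
// conn:  glio_E, glio_I (0/1 per neuron: contacted by astrocytes),
//        recv_A (0/1 per astrocyte: receives neuronal input).
//
// Returns the final state, the raster of this stretch, sampled population
// traces, and event-conservation diagnostics.

// [[Rcpp::export]]
List spiking_core(List state, List par, List conn, int n_steps, double dt,
                  int record_every, bool record_raster, double noise_seed) {
  NumericVector V_E = clone(as<NumericVector>(state["V_E"]));
  NumericVector V_I = clone(as<NumericVector>(state["V_I"]));
  NumericVector G_A = clone(as<NumericVector>(state["G_A"]));
  NumericVector I_a = clone(as<NumericVector>(state["I_a"]));
  NumericVector u = clone(as<NumericVector>(state["u"]));
  NumericVector s = clone(as<NumericVector>(state["s"]));
  NumericVector q_E = clone(as<NumericVector>(state["q_E"]));
  NumericVector q_I = clone(as<NumericVector>(state["q_I"]));
  NumericVector q_A = clone(as<NumericVector>(state["q_A"]));
  IntegerVector head = clone(as<IntegerVector>(state["head"]));
  double t = as<double>(state["t_ms"]);

  const int N_E = V_E.size(), N_I = V_I.size(), N_A = G_A.size();
  IntegerVector glio_E = conn["glio_E"], glio_I = conn["glio_I"],
                recv_A = conn["recv_A"];

  const double tau_E = par["tau_E"], tau_I = par["tau_I"],
               tau_A = par["tau_A"], tau_a = par["tau_a"];
  const double J_EE = par["J_EE"], J_EI = par["J_EI"], J_EA = par["J_EA"],
               J_IE = par["J_IE"], J_II = par["J_II"], J_IA = par["J_IA"],
               J_AE = par["J_AE"], J_AI = par["J_AI"], J_AA = par["J_AA"];
  const double beta = par["beta"], K_a = par["K_a"];
  const double sig_E = par["sigma_E"], sig_I = par["sigma_I"],
               sig_A = par["sigma_A"];
  const double V_r = par["V_r"], V_th = par["V_th"];
  const double V_L_E = par["V_L_E"], V_L_I = par["V_L_I"];
  const double G_r = par["G_r"], G_th = par["G_th"], G_L = par["G_L"];
  NumericVector tau_bar = par["tau_bar"];   // E, I, A
  NumericVector tau_r = par["tau_r"], tau_d = par["tau_d"];
  NumericVector d_min = par["d_min"], d_max = par["d_max"];

  const double cE = dt / tau_E, cI = dt / tau_I, cA = dt / tau_A;
  const double nE = sig_E * std::sqrt(dt / tau_E);
  const double nI = sig_I * std::sqrt(dt / tau_I);
  const double nA = sig_A * std::sqrt(dt / tau_A);
  const double ahp_inc = beta / tau_a;

  Xoshiro rng((uint64_t)noise_seed);

  NumericVector* q[3] = { &q_E, &q_I, &q_A };
  const int qlen[3] = { (int)q_E.size(), (int)q_I.size(), (int)q_A.size() };

  double* vE = V_E.begin(); double* vI = V_I.begin();
  double* gA = G_A.begin(); double* ia = I_a.begin();
  const int* gE = glio_E.begin(); const int* gI = glio_I.begin();
  const int* rA = recv_A.begin();
  double* qp[3] = { q_E.begin(), q_I.begin(), q_A.begin() };

  std::vector<int> ras_pop, ras_cell;
  std::vector<double> ras_t;
  if (record_raster) {
    ras_pop.reserve(1 << 16); ras_cell.reserve(1 << 16);
    ras_t.reserve(1 << 16);
  }
  long spikes[3] = { 0, 0, 0 }, matured[3] = { 0, 0, 0 };

  const int n_rec = n_steps / record_every + 1;
  NumericMatrix traces(n_rec, 11);
  int rec_row = 0;
  double mean_ahp = 0.0;
  for (int i = 0; i < N_E; ++i) mean_ahp += I_a[i];
  mean_ahp = K_a * mean_ahp / N_E;
  traces(0, 0) = t;
  traces(0, 1) = u[0]; traces(0, 2) = u[1]; traces(0, 3) = u[2];
  traces(0, 4) = s[0]; traces(0, 5) = s[1]; traces(0, 6) = s[2];
  traces(0, 7) = mean_ahp;
  traces(0, 8) = N_E ? V_E[0] : NA_REAL;
  traces(0, 9) = N_I ? V_I[0] : NA_REAL;
  traces(0, 10) = N_A ? G_A[0] : NA_REAL;
  ++rec_row;

  for (int k = 0; k < n_steps; ++k) {
    const double t_next = t + dt;
    const double rec_E = J_EE * s[0] + J_EI * s[1];
    const double rec_I = J_IE * s[0] + J_II * s[1];
    const double rec_A = J_AA * s[2];
    const double glio_to_E = J_EA * s[2], glio_to_I = J_IA * s[2];
    const double neuro_to_A = J_AE * s[0] + J_AI * s[1];

    double ahp_sum = 0.0;

    const double decay_a = dt / tau_a;
    const double base_E = cE * V_L_E + cE * rec_E;
    const double keep_E = 1.0 - cE;
    const double base_I = cI * V_L_I + cI * rec_I;
    const double keep_I = 1.0 - cI;
    const double base_A = cA * G_L + cA * rec_A;
    const double keep_A = 1.0 - cA;

    for (int i = 0; i < N_E; ++i) {
      double v = keep_E * vE[i] + base_E +
        cE * ((gE[i] ? glio_to_E : 0.0) - K_a * ia[i]);
      if (nE > 0.0) v += nE * zigg.draw(rng);
      ia[i] -= decay_a * ia[i];
      if (v >= V_th) {
        v = V_r;
        ia[i] += ahp_inc;
        const double d = d_min[0] + rng.unif() * (d_max[0] - d_min[0]);
        const int bin = (int)std::lround(d / dt);
        qp[0][(head[0] + bin) % qlen[0]] += 1.0;
        ++spikes[0];
        if (record_raster) {
          ras_pop.push_back(0); ras_cell.push_back(i + 1);
          ras_t.push_back(t_next);
        }
      }
      vE[i] = v;
      ahp_sum += ia[i];
    }

    for (int i = 0; i < N_I; ++i) {
      double v = keep_I * vI[i] + base_I + cI * (gI[i] ? glio_to_I : 0.0);
      if (nI > 0.0) v += nI * zigg.draw(rng);
      if (v >= V_th) {
        v = V_r;
        const double d = d_min[1] + rng.unif() * (d_max[1] - d_min[1]);
        const int bin = (int)std::lround(d / dt);
        qp[1][(head[1] + bin) % qlen[1]] += 1.0;
        ++spikes[1];
        if (record_raster) {
          ras_pop.push_back(1); ras_cell.push_back(i + 1);
          ras_t.push_back(t_next);
        }
      }
      vI[i] = v;
    }

    for (int i = 0; i < N_A; ++i) {
      double g = keep_A * gA[i] + base_A + cA * (rA[i] ? neuro_to_A : 0.0);
      if (nA > 0.0) g += nA * zigg.draw(rng);
      if (g >= G_th) {
        g = G_r;
        const double d = d_min[2] + rng.unif() * (d_max[2] - d_min[2]);
        const int bin = (int)std::lround(d / dt);
        qp[2][(head[2] + bin) % qlen[2]] += 1.0;
        ++spikes[2];
        if (record_raster) {
          ras_pop.push_back(2); ras_cell.push_back(i + 1);
          ras_t.push_back(t_next);
        }
      }
      gA[i] = g;
    }

    // mature delayed events (delay 0 matures within the same step), then
    // advance the population synapse variables
    for (int p = 0; p < 3; ++p) {
      const double arriving = qp[p][head[p]];
      qp[p][head[p]] = 0.0;
      head[p] = (head[p] + 1) % qlen[p];
      matured[p] += (long)std::lround(arriving);
      const double u_old = u[p];
      u[p] += dt / tau_r[p] * (-u_old) + arriving * tau_bar[p] / tau_r[p];
      s[p] += dt / tau_d[p] * (-s[p] + u_old);
    }

    t = t_next;

    if (!R_FINITE(vE[0]) || !R_FINITE(s[0]) || !R_FINITE(s[2]))
      stop("numerical blow-up at t = %f ms", t);

    if ((k + 1) % record_every == 0) {
      traces(rec_row, 0) = t;
      traces(rec_row, 1) = u[0]; traces(rec_row, 2) = u[1];
      traces(rec_row, 3) = u[2];
      traces(rec_row, 4) = s[0]; traces(rec_row, 5) = s[1];
      traces(rec_row, 6) = s[2];
      traces(rec_row, 7) = N_E ? K_a * ahp_sum / N_E : NA_REAL;
      traces(rec_row, 8) = N_E ? vE[0] : NA_REAL;
      traces(rec_row, 9) = N_I ? vI[0] : NA_REAL;
      traces(rec_row, 10) = N_A ? gA[0] : NA_REAL;
      ++rec_row;
    }
  }

  double pending[3];
  for (int p = 0; p < 3; ++p) {
    double tot = 0.0;
    for (int b = 0; b < qlen[p]; ++b) tot += (*q[p])[b];
    pending[p] = tot;
  }

  List out_state = List::create(
    _["V_E"] = V_E, _["V_I"] = V_I, _["G_A"] = G_A, _["I_a"] = I_a,
    _["u"] = u, _["s"] = s, _["q_E"] = q_E, _["q_I"] = q_I, _["q_A"] = q_A,
    _["head"] = head, _["t_ms"] = t);

  return List::create(
    _["state"] = out_state,
    _["raster_pop"] = wrap(ras_pop),
    _["raster_cell"] = wrap(ras_cell),
    _["raster_t"] = wrap(ras_t),
    _["traces"] = traces,
    _["spikes"] = NumericVector::create(spikes[0], spikes[1], spikes[2]),
    _["matured"] = NumericVector::create(matured[0], matured[1], matured[2]),
    _["pending"] = NumericVector::create(pending[0], pending[1], pending[2]));
}
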