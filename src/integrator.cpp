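#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// State layout: y = (Re phiD, Im phiD, Re phiA, Im phiA, uz, pz, ux, px).
// hbar = 1, unit oscillator masses; time in units of 1/hbar.

struct Pars {
  double ED, EA, kz, kx, ex, Oz2, Ox2, gz, gx;
};

static inline void rhs(const double* y, double* dy, const Pars& p,
                       double eta_z, double eta_x) {
  const double dr = y[0], di = y[1], ar = y[2], ai = y[3];
  const double uz = y[4], pz = y[5], ux = y[6], px = y[7];
  const double hD = p.ED - p.kz * uz;
  const double hA = p.EA + p.kz * uz;
  const double g  = p.ex + p.kx * ux;     // effective transfer integral
  // i phi' = H phi  =>  Re' = (H phi)_Im, Im' = -(H phi)_Re
  dy[0] =  hD * di + g * ai;
  dy[1] = -(hD * dr + g * ar);
  dy[2] =  hA * ai + g * di;
  dy[3] = -(hA * ar + g * dr);
  const double C = (ar * ar + ai * ai) - (dr * dr + di * di); // |phiA|^2-|phiD|^2
  const double X = 2.0 * (dr * ar + di * ai);                 // 2 Re(phiD* phiA)
  dy[4] = pz;
  dy[5] = -p.gz * pz - p.Oz2 * uz - p.kz * C + eta_z;
  dy[6] = px;
  dy[7] = -p.gx * px - p.Ox2 * ux - p.kx * X + eta_x;
}

static inline double energy_of(const double* y, const Pars& p) {
  const double dr = y[0], di = y[1], ar = y[2], ai = y[3];
  const double uz = y[4], pz = y[5], ux = y[6], px = y[7];
  const double nD = dr * dr + di * di, nA = ar * ar + ai * ai;
  const double X = 2.0 * (dr * ar + di * ai);
  return p.ED * nD + p.EA * nA + p.kz * uz * (nA - nD) + (p.ex + p.kx * ux) * X
       + 0.5 * pz * pz + 0.5 * p.Oz2 * uz * uz
       + 0.5 * px * px + 0.5 * p.Ox2 * ux * ux;
}

// Dormand-Prince 5(4) tableau (fixed step; the embedded 4th-order solution is
// used only as an accuracy diagnostic, never for step-size control, so the
// per-step frozen noise force keeps its stated variance).
static const double c2 = 1.0 / 5.0, c3 = 3.0 / 10.0, c4 = 4.0 / 5.0,
                    c5 = 8.0 / 9.0;
static const double a21 = 1.0 / 5.0;
static const double a31 = 3.0 / 40.0, a32 = 9.0 / 40.0;
static const double a41 = 44.0 / 45.0, a42 = -56.0 / 15.0, a43 = 32.0 / 9.0;
static const double a51 = 19372.0 / 6561.0, a52 = -25360.0 / 2187.0,
                    a53 = 64448.0 / 6561.0, a54 = -212.0 / 729.0;
static const double a61 = 9017.0 / 3168.0, a62 = -355.0 / 33.0,
                    a63 = 46732.0 / 5247.0, a64 = 49.0 / 176.0,
                    a65 = -5103.0 / 18656.0;
static const double b1 = 35.0 / 384.0, b3 = 500.0 / 1113.0,
                    b4 = 125.0 / 192.0, b5 = -2187.0 / 6784.0, b6 = 11.0 / 84.0;
static const double e1 = 5179.0 / 57600.0, e3 = 7571.0 / 16695.0,
                    e4 = 393.0 / 640.0, e5 = -92097.0 / 339200.0,
                    e6 = 187.0 / 2100.0, e7 = 1.0 / 40.0;

// [[Rcpp::export]]
List integrate_core(NumericVector y0, NumericVector par, double kBT,
                    double dt, int n_steps, int stride,
                    bool renormalize, double norm_tol) {
  Pars p;
  p.ED = par["E_D"]; p.EA = par["E_A"];
  p.kz = par["k_z"]; p.kx = par["k_x"]; p.ex = par["eps_x"];
  const double Oz = par["Omega_z"], Ox = par["Omega_x"];
  p.Oz2 = Oz * Oz; p.Ox2 = Ox * Ox;
  p.gz = par["gamma_z"]; p.gx = par["gamma_x"];

  const bool noisy = kBT > 0.0;
  const double sd_z = noisy ? std::sqrt(2.0 * p.gz * kBT / dt) : 0.0;
  const double sd_x = noisy ? std::sqrt(2.0 * p.gx * kBT / dt) : 0.0;

  double y[8];
  for (int i = 0; i < 8; ++i) y[i] = y0[i];

  const int n_samp = n_steps / stride + 1 + (n_steps % stride ? 1 : 0);
  NumericVector t_out(n_samp);
  NumericMatrix Y(n_samp, 8);
  NumericVector E_out(n_samp), PD(n_samp), PA(n_samp);

  double k1[8], k2[8], k3[8], k4[8], k5[8], k6[8], k7[8], yt[8], y5[8];
  double max_norm_dev = 0.0, max_embed_err = 0.0;
  long n_sign_flips = 0;

  int is = 0;
  t_out[is] = 0.0;
  for (int i = 0; i < 8; ++i) Y(is, i) = y[i];
  PD[is] = y[0] * y[0] + y[1] * y[1];
  PA[is] = y[2] * y[2] + y[3] * y[3];
  E_out[is] = energy_of(y, p);
  ++is;

  for (int step = 1; step <= n_steps; ++step) {
    double ez = 0.0, exn = 0.0;
    if (noisy) {             // one draw per macro-step, order (eta_z, eta_x),
      ez  = sd_z * norm_rand();  // frozen across the internal RK stages
      exn = sd_x * norm_rand();
    }
    rhs(y, k1, p, ez, exn);
    for (int i = 0; i < 8; ++i) yt[i] = y[i] + dt * a21 * k1[i];
    rhs(yt, k2, p, ez, exn);
    for (int i = 0; i < 8; ++i)
      yt[i] = y[i] + dt * (a31 * k1[i] + a32 * k2[i]);
    rhs(yt, k3, p, ez, exn);
    for (int i = 0; i < 8; ++i)
      yt[i] = y[i] + dt * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    rhs(yt, k4, p, ez, exn);
    for (int i = 0; i < 8; ++i)
      yt[i] = y[i] + dt * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i]
                           + a54 * k4[i]);
    rhs(yt, k5, p, ez, exn);
    for (int i = 0; i < 8; ++i)
      yt[i] = y[i] + dt * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i]
                           + a64 * k4[i] + a65 * k5[i]);
    rhs(yt, k6, p, ez, exn);
    for (int i = 0; i < 8; ++i)
      y5[i] = y[i] + dt * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i]
                           + b5 * k5[i] + b6 * k6[i]);
    rhs(y5, k7, p, ez, exn);
    for (int i = 0; i < 8; ++i) {
      const double y4 = y[i] + dt * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i]
                                     + e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      const double d = std::fabs(y5[i] - y4);
      if (d > max_embed_err) max_embed_err = d;
      y[i] = y5[i];
    }

    double nrm = y[0] * y[0] + y[1] * y[1] + y[2] * y[2] + y[3] * y[3];
    double dev = std::fabs(nrm - 1.0);
    if (dev > max_norm_dev) max_norm_dev = dev;
    if (renormalize) {
      const double s = 1.0 / std::sqrt(nrm);
      for (int i = 0; i < 4; ++i) y[i] *= s;
    } else if (dev > norm_tol) {
      stop("electronic norm drift %.3e exceeds tolerance %.3e at t = %.6f",
           dev, norm_tol, step * dt);
    }
    for (int i = 0; i < 8; ++i) {
      if (!R_finite(y[i]))
        stop("non-finite state component at t = %.6f", step * dt);
    }
    // linear-coupling caveat: sign change of the effective transfer integral
    if (p.ex != 0.0 && (p.ex + p.kx * y[6]) * p.ex <= 0.0) ++n_sign_flips;

    if (step % stride == 0 || step == n_steps) {
      t_out[is] = step * dt;
      for (int i = 0; i < 8; ++i) Y(is, i) = y[i];
      PD[is] = y[0] * y[0] + y[1] * y[1];
      PA[is] = y[2] * y[2] + y[3] * y[3];
      E_out[is] = energy_of(y, p);
      ++is;
    }
  }

  if (is < n_samp) {  // n_steps divisible by stride: no extra final sample
    t_out = head(t_out, is);
    E_out = head(E_out, is);
    PD = head(PD, is);
    PA = head(PA, is);
    Y = Y(Range(0, is - 1), _);
  }

  return List::create(
    _["times"] = t_out, _["Y"] = Y, _["P_D"] = PD, _["P_A"] = PA,
    _["energy"] = E_out,
    _["final_norm"] = y[0] * y[0] + y[1] * y[1] + y[2] * y[2] + y[3] * y[3],
    _["max_norm_dev"] = max_norm_dev,
    _["max_embed_err"] = max_embed_err,
    _["n_sign_flips"] = (double) n_sign_flips);
}
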