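// Minimal-model ODE kernels.
//
// State y = (G, X):
//   dG/dt = -(GEZI + X) * G + (GEZI + Xb) * Gb,   G(0) = Gb + Dose/V
//   dX/dt = -p2 * X + p2 * SI * I(t),             X(0) = SI * Ib
// with I(t) the piecewise-linear insulin forcing (constant beyond the
// measured range) and Xb = SI * Ib.
//
// The production solver is adaptive Dormand-Prince RK45 with the forcing
// knots and requested output times as mandatory step boundaries, so the
// integrator never steps across a derivative kink.  A naive fixed-step RK4
// integrator is kept as a deliberately independent cross-check.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct MMSys {
  double GEZI, SI, p2, V;
  double Gb, Ib, Xb;
  const double *tk, *ck;  // insulin knots
  int nk;
};

static inline double ins_at(const MMSys &s, double t) {
  if (t <= s.tk[0]) return s.ck[0];
  if (t >= s.tk[s.nk - 1]) return s.ck[s.nk - 1];
  int lo = 0, hi = s.nk - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (s.tk[mid] <= t) lo = mid; else hi = mid;
  }
  double w = (t - s.tk[lo]) / (s.tk[hi] - s.tk[lo]);
  return s.ck[lo] + w * (s.ck[hi] - s.ck[lo]);
}

static inline void deriv(const MMSys &s, double t, const double y[2], double f[2]) {
  double I = ins_at(s, t);
  f[0] = -(s.GEZI + y[1]) * y[0] + (s.GEZI + s.Xb) * s.Gb;
  f[1] = -s.p2 * y[1] + s.p2 * s.SI * I;
}

// Dormand-Prince 5(4) coefficients
static const double C2 = 1.0 / 5, C3 = 3.0 / 10, C4 = 4.0 / 5, C5 = 8.0 / 9;
static const double A21 = 1.0 / 5;
static const double A31 = 3.0 / 40, A32 = 9.0 / 40;
static const double A41 = 44.0 / 45, A42 = -56.0 / 15, A43 = 32.0 / 9;
static const double A51 = 19372.0 / 6561, A52 = -25360.0 / 2187,
                    A53 = 64448.0 / 6561, A54 = -212.0 / 729;
static const double A61 = 9017.0 / 3168, A62 = -355.0 / 33,
                    A63 = 46732.0 / 5247, A64 = 49.0 / 176, A65 = -5103.0 / 18656;
static const double B1 = 35.0 / 384, B3 = 500.0 / 1113, B4 = 125.0 / 192,
                    B5 = -2187.0 / 6784, B6 = 11.0 / 84;
static const double E1 = 71.0 / 57600, E3 = -71.0 / 16695, E4 = 71.0 / 1920,
                    E5 = -17253.0 / 339200, E6 = 22.0 / 525, E7 = -1.0 / 40;

// Integrate from ta to tb (insulin linear segments handled via ins_at; the
// caller guarantees no knot lies strictly inside [ta, tb]).
static bool advance(const MMSys &s, double ta, double tb, double y[2],
                    double rtol, double atol, double &h, long &nstep) {
  double t = ta;
  while (t < tb) {
    if (h > tb - t) h = tb - t;
    if (h < 1e-12) h = 1e-12;
    double k1[2], k2[2], k3[2], k4[2], k5[2], k6[2], k7[2], yt[2], y5[2];
    deriv(s, t, y, k1);
    for (int i = 0; i < 2; ++i) yt[i] = y[i] + h * A21 * k1[i];
    deriv(s, t + C2 * h, yt, k2);
    for (int i = 0; i < 2; ++i) yt[i] = y[i] + h * (A31 * k1[i] + A32 * k2[i]);
    deriv(s, t + C3 * h, yt, k3);
    for (int i = 0; i < 2; ++i) yt[i] = y[i] + h * (A41 * k1[i] + A42 * k2[i] + A43 * k3[i]);
    deriv(s, t + C4 * h, yt, k4);
    for (int i = 0; i < 2; ++i)
      yt[i] = y[i] + h * (A51 * k1[i] + A52 * k2[i] + A53 * k3[i] + A54 * k4[i]);
    deriv(s, t + C5 * h, yt, k5);
    for (int i = 0; i < 2; ++i)
      yt[i] = y[i] + h * (A61 * k1[i] + A62 * k2[i] + A63 * k3[i] + A64 * k4[i] + A65 * k5[i]);
    deriv(s, t + h, yt, k6);
    for (int i = 0; i < 2; ++i)
      y5[i] = y[i] + h * (B1 * k1[i] + B3 * k3[i] + B4 * k4[i] + B5 * k5[i] + B6 * k6[i]);
    deriv(s, t + h, y5, k7);
    double err = 0.0;
    for (int i = 0; i < 2; ++i) {
      double e = h * (E1 * k1[i] + E3 * k3[i] + E4 * k4[i] + E5 * k5[i] +
                      E6 * k6[i] + E7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double r = e / sc;
      err += r * r;
    }
    err = std::sqrt(err / 2.0);
    if (!std::isfinite(err)) return false;
    if (err <= 1.0) {
      t += h;
      y[0] = y5[0];
      y[1] = y5[1];
    }
    double fac = 0.9 * std::pow(err > 1e-10 ? err : 1e-10, -0.2);
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    h *= fac;
    if (++nstep > 2000000L) return false;
  }
  return true;
}

static bool mm_solve(const MMSys &s, double dose,
                     const double *times, int nt,
                     double rtol, double atol,
                     double *outG, double *outX) {
  double y[2];
  y[0] = s.Gb + dose / s.V;
  y[1] = s.SI * s.Ib;
  double tmax = times[nt - 1];
  // merged stop points: forcing knots in (0, tmax) plus output times
  std::vector<double> stops;
  stops.reserve(nt + s.nk);
  for (int i = 0; i < nt; ++i) stops.push_back(times[i]);
  for (int i = 0; i < s.nk; ++i)
    if (s.tk[i] > 0 && s.tk[i] < tmax) stops.push_back(s.tk[i]);
  std::sort(stops.begin(), stops.end());
  stops.erase(std::unique(stops.begin(), stops.end()), stops.end());

  double t = 0.0, h = 0.5;
  long nstep = 0;
  int iout = 0;
  for (size_t k = 0; k < stops.size(); ++k) {
    double tb = stops[k];
    if (tb > t) {
      if (!advance(s, t, tb, y, rtol, atol, h, nstep)) return false;
      t = tb;
    }
    while (iout < nt && times[iout] <= t) {
      outG[iout] = y[0];
      outX[iout] = y[1];
      ++iout;
    }
  }
  while (iout < nt) {  // times at or before 0
    outG[iout] = s.Gb + dose / s.V;
    outX[iout] = s.SI * s.Ib;
    ++iout;
  }
  return true;
}

static MMSys make_sys(double GEZI, double SI, double p2, double V,
                      double Gb, double Ib,
                      const NumericVector &ins_t, const NumericVector &ins_c) {
  MMSys s;
  s.GEZI = GEZI; s.SI = SI; s.p2 = p2; s.V = V;
  s.Gb = Gb; s.Ib = Ib; s.Xb = SI * Ib;
  s.tk = ins_t.begin(); s.ck = ins_c.begin(); s.nk = ins_t.size();
  return s;
}

// [[Rcpp::export]]
NumericMatrix mm_simulate_cpp(NumericVector theta, double dose, double Gb,
                              double Ib, NumericVector ins_t, NumericVector ins_c,
                              NumericVector times, double rtol, double atol) {
  int nt = times.size();
  MMSys s = make_sys(theta[0], theta[1], theta[2], theta[3], Gb, Ib, ins_t, ins_c);
  NumericMatrix out(nt, 2);
  std::vector<double> g(nt), x(nt);
  if (!mm_solve(s, dose, times.begin(), nt, rtol, atol, g.data(), x.data()))
    stop("minimal-model ODE solver failed (step limit or non-finite state); "
         "check parameter values and forcing");
  for (int i = 0; i < nt; ++i) { out(i, 0) = g[i]; out(i, 1) = x[i]; }
  colnames(out) = CharacterVector::create("G", "X");
  return out;
}

// Batched observation log-likelihood under a proportional-SD error model:
// y_j ~ N(f_j, (sigma * f_j)^2).  One row of `logtheta` per parameter draw
// (log GEZI, log SI, log p2, log V).  Returns loglik, the relative residual
// sum of squares, and sum(log f_j); failed solves yield -Inf loglik.
// [[Rcpp::export]]
NumericMatrix mm_loglik_cpp(NumericMatrix logtheta, double dose, double Gb,
                            double Ib, NumericVector ins_t, NumericVector ins_c,
                            NumericVector obs_t, NumericVector obs_y,
                            double sigma, double rtol, double atol) {
  int M = logtheta.nrow(), n = obs_t.size();
  NumericMatrix out(M, 3);
  colnames(out) = CharacterVector::create("loglik", "ssr_rel", "sum_log_f");
  std::vector<double> g(n), x(n);
  const double l2pi = std::log(2.0 * M_PI);
  for (int m = 0; m < M; ++m) {
    MMSys s = make_sys(std::exp(logtheta(m, 0)), std::exp(logtheta(m, 1)),
                       std::exp(logtheta(m, 2)), std::exp(logtheta(m, 3)),
                       Gb, Ib, ins_t, ins_c);
    bool ok = mm_solve(s, dose, obs_t.begin(), n, rtol, atol, g.data(), x.data());
    double ssr = 0.0, slf = 0.0;
    if (ok) {
      for (int j = 0; j < n; ++j) {
        if (!(g[j] > 0.0) || !std::isfinite(g[j])) { ok = false; break; }
        double r = (obs_y[j] - g[j]) / g[j];
        ssr += r * r;
        slf += std::log(g[j]);
      }
    }
    if (!ok) {
      out(m, 0) = R_NegInf; out(m, 1) = NA_REAL; out(m, 2) = NA_REAL;
    } else {
      out(m, 0) = -0.5 * n * l2pi - n * std::log(sigma) - slf - ssr / (2.0 * sigma * sigma);
      out(m, 1) = ssr;
      out(m, 2) = slf;
    }
  }
  return out;
}

// Independent brute-force oracle: classical RK4 with a fixed step, insulin
// interpolated afresh at every stage.  Shares nothing with the adaptive path
// beyond the derivative definition.
// [[Rcpp::export]]
NumericMatrix mm_simulate_fixed_cpp(NumericVector theta, double dose, double Gb,
                                    double Ib, NumericVector ins_t,
                                    NumericVector ins_c, NumericVector times,
                                    double h) {
  int nt = times.size();
  MMSys s = make_sys(theta[0], theta[1], theta[2], theta[3], Gb, Ib, ins_t, ins_c);
  NumericMatrix out(nt, 2);
  colnames(out) = CharacterVector::create("G", "X");
  double y[2] = {Gb + dose / s.V, s.SI * Ib};
  double t = 0.0, tmax = times[nt - 1];
  int iout = 0;
  while (iout < nt && times[iout] <= 0.0) {
    out(iout, 0) = y[0]; out(iout, 1) = y[1]; ++iout;
  }
  double yprev[2];
  double tprev = 0.0;
  while (t < tmax && iout < nt) {
    yprev[0] = y[0]; yprev[1] = y[1]; tprev = t;
    double hh = std::min(h, tmax - t);
    double k1[2], k2[2], k3[2], k4[2], yt[2];
    deriv(s, t, y, k1);
    for (int i = 0; i < 2; ++i) yt[i] = y[i] + 0.5 * hh * k1[i];
    deriv(s, t + 0.5 * hh, yt, k2);
    for (int i = 0; i < 2; ++i) yt[i] = y[i] + 0.5 * hh * k2[i];
    deriv(s, t + 0.5 * hh, yt, k3);
    for (int i = 0; i < 2; ++i) yt[i] = y[i] + hh * k3[i];
    deriv(s, t + hh, yt, k4);
    for (int i = 0; i < 2; ++i)
      y[i] += hh / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    t += hh;
    while (iout < nt && times[iout] <= t + 1e-12) {
      double w = (times[iout] - tprev) / (t - tprev);
      out(iout, 0) = yprev[0] + w * (y[0] - yprev[0]);
      out(iout, 1) = yprev[1] + w * (y[1] - yprev[1]);
      ++iout;
    }
  }
  return out;
}
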