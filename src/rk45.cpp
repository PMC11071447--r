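#include <Rcpp.h>
#include <cmath>

// Five-species immunoagglutination mass-action kinetics.
// State ordering: y[0]=Abp, y[1]=Ag, y[2]=Abp.Ag, y[3]=Abp2.Ag, y[4]=Abp.Ag2
// Parameters: k[0]=kon1, k[1]=koff1, k[2]=kon2, k[3]=koff2, k[4]=kon3
// Abp.Ag2 has a production term only (its dissociation is not modelled); it
// is carried so that both mass balances close.
static inline void agg_rhs(const double* y, const double* k, double* dy) {
  const double A = y[0], G = y[1], C1 = y[2], C2 = y[3];
  const double v1 = k[0] * A * G;    // Abp + Ag -> Abp.Ag
  const double r1 = k[1] * C1;       // Abp.Ag -> Abp + Ag
  const double v2 = k[2] * A * C1;   // Abp + Abp.Ag -> Abp2.Ag
  const double r2 = k[3] * C2;       // Abp2.Ag -> Abp + Abp.Ag
  const double v3 = k[4] * C1 * G;   // Ag + Abp.Ag -> Abp.Ag2
  dy[0] = -v1 + r1 - v2 + r2;
  dy[1] = -v1 + r1 - v3;
  dy[2] =  v1 - r1 - v2 + r2 - v3;
  dy[3] =  v2 - r2;
  dy[4] =  v3;
}

// [[Rcpp::export(name = ".agg_rhs_cpp")]]
Rcpp::NumericVector agg_rhs_cpp(Rcpp::NumericVector y, Rcpp::NumericVector k) {
  Rcpp::NumericVector dy(5);
  agg_rhs(y.begin(), k.begin(), dy.begin());
  return dy;
}

// Adaptive Dormand-Prince 5(4) integration of the agglutination system,
// reporting the state at each requested output time. Output times must be
// non-negative and strictly increasing. Error control per component:
// sc_i = atol + rtol * |y_i|, accept when the RMS of e_i/sc_i is <= 1.
// [[Rcpp::export(name = ".agg_integrate_cpp")]]
Rcpp::NumericMatrix agg_integrate_cpp(Rcpp::NumericVector y0,
                                      Rcpp::NumericVector k,
                                      Rcpp::NumericVector times,
                                      double rtol, double atol) {
  const int n = 5, nt = times.size();
  if (y0.size() != n) Rcpp::stop("state must have 5 components");
  if (k.size() != 5) Rcpp::stop("5 rate constants expected");

  // Dormand-Prince RK5(4)7M tableau
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5,
                      c5 = 8.0 / 9;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  // embedded 4th-order weights
  static const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695,
                      e4 = 393.0 / 640, e5 = -92097.0 / 339200,
                      e6 = 187.0 / 2100, e7 = 1.0 / 40;

  Rcpp::NumericMatrix out(nt, n);
  double y[5], yt[5], y5[5];
  double k1[5], k2[5], k3[5], k4[5], k5[5], k6[5], k7[5];
  for (int i = 0; i < n; ++i) y[i] = y0[i];

  double t = 0.0;
  const double t_end = times[nt - 1];
  double h = t_end / 100.0;
  if (h <= 0) Rcpp::stop("final output time must be positive");
  // crude initial step bound from the rate scale
  double rate = 0.0;
  agg_rhs(y, k.begin(), k1);
  for (int i = 0; i < n; ++i) rate = std::max(rate, std::fabs(k1[i]));
  if (rate > 0) h = std::min(h, 0.1 / rate);

  int iout = 0;
  while (iout < nt && times[iout] <= t) {  // report t = 0 if requested
    for (int i = 0; i < n; ++i) out(iout, i) = y[i];
    ++iout;
  }

  long nstep = 0;
  const long max_steps = 50000000L;
  bool k1_fresh = true;  // k1 already holds f(t, y)
  while (iout < nt) {
    if (++nstep > max_steps) Rcpp::stop("integration failed: step limit hit");
    if (t + h > t_end) h = t_end - t;
    bool hit_out = false;
    if (t + h >= times[iout]) { h = times[iout] - t; hit_out = true; }
    if (h <= 1e-14 * std::max(1.0, t)) Rcpp::stop("integration failed: step size underflow");

    if (!k1_fresh) agg_rhs(y, k.begin(), k1);
    for (int i = 0; i < n; ++i) yt[i] = y[i] + h * a21 * k1[i];
    agg_rhs(yt, k.begin(), k2);
    for (int i = 0; i < n; ++i) yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    agg_rhs(yt, k.begin(), k3);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    agg_rhs(yt, k.begin(), k4);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    agg_rhs(yt, k.begin(), k5);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
    agg_rhs(yt, k.begin(), k6);
    for (int i = 0; i < n; ++i)
      y5[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                          b5 * k5[i] + b6 * k6[i]);
    agg_rhs(y5, k.begin(), k7);

    double err = 0.0;
    for (int i = 0; i < n; ++i) {
      double y4 = y[i] + h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                              e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double e = (y5[i] - y4) / sc;
      err += e * e;
    }
    err = std::sqrt(err / n);

    if (err <= 1.0) {  // accept
      t += h;
      for (int i = 0; i < n; ++i) {
        y[i] = y5[i];
        if (y[i] < 0) {
          if (y[i] < -1e3 * atol)
            Rcpp::stop("integration failed: negative concentration beyond tolerance");
          y[i] = 0.0;
        }
        k1[i] = k7[i];  // FSAL
      }
      k1_fresh = true;
      if (hit_out) {
        for (int i = 0; i < n; ++i) out(iout, i) = y[i];
        ++iout;
      }
    } else {
      k1_fresh = false;
      hit_out = false;
    }
    double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
    h *= std::min(5.0, std::max(0.2, fac));
  }
  return out;
}
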