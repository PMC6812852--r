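#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step RK4 kernels for the activation models. All kernels take the
// already-shaped, uniformly sampled excitation u[0..n-1] and return the state
// sampled on the same grid. Mid-step input values are linear interpolations
// (average of the bracketing samples), so the schemes keep their full order
// on the smooth segments between pulses.

// Hatze-Zakotnik cascade: beta'' + th1 beta' + th2 beta = alpha(t),
// gamma'' + th3 gamma' + c(t) th4 gamma = beta(t).
// cvec holds the piecewise-constant potentiation factor per sample.
// [[Rcpp::export]]
NumericVector cpp_rk4_hatze(NumericVector alpha, NumericVector cvec,
                            NumericVector theta, double dt) {
  int n = alpha.size();
  NumericVector out(n);
  double th1 = theta[0], th2 = theta[1], th3 = theta[2], th4 = theta[3];
  double y0 = 0, y1 = 0, y2 = 0, y3 = 0; // beta, beta', gamma, gamma'
  out[0] = 0.0;
  for (int k = 0; k < n - 1; ++k) {
    double a0 = alpha[k], a1 = alpha[k + 1], am = 0.5 * (a0 + a1);
    double cc = cvec[k] * th4;
    double k1_0, k1_1, k1_2, k1_3, k2_0, k2_1, k2_2, k2_3;
    double k3_0, k3_1, k3_2, k3_3, k4_0, k4_1, k4_2, k4_3;
    // f(y, a) = (y1, a - th1 y1 - th2 y0, y3, y0 - th3 y3 - cc y2)
    k1_0 = y1; k1_1 = a0 - th1 * y1 - th2 * y0;
    k1_2 = y3; k1_3 = y0 - th3 * y3 - cc * y2;
    double t0 = y0 + 0.5 * dt * k1_0, t1 = y1 + 0.5 * dt * k1_1;
    double t2 = y2 + 0.5 * dt * k1_2, t3 = y3 + 0.5 * dt * k1_3;
    k2_0 = t1; k2_1 = am - th1 * t1 - th2 * t0;
    k2_2 = t3; k2_3 = t0 - th3 * t3 - cc * t2;
    t0 = y0 + 0.5 * dt * k2_0; t1 = y1 + 0.5 * dt * k2_1;
    t2 = y2 + 0.5 * dt * k2_2; t3 = y3 + 0.5 * dt * k2_3;
    k3_0 = t1; k3_1 = am - th1 * t1 - th2 * t0;
    k3_2 = t3; k3_3 = t0 - th3 * t3 - cc * t2;
    t0 = y0 + dt * k3_0; t1 = y1 + dt * k3_1;
    t2 = y2 + dt * k3_2; t3 = y3 + dt * k3_3;
    k4_0 = t1; k4_1 = a1 - th1 * t1 - th2 * t0;
    k4_2 = t3; k4_3 = t0 - th3 * t3 - cc * t2;
    y0 += dt / 6.0 * (k1_0 + 2 * k2_0 + 2 * k3_0 + k4_0);
    y1 += dt / 6.0 * (k1_1 + 2 * k2_1 + 2 * k3_1 + k4_1);
    y2 += dt / 6.0 * (k1_2 + 2 * k2_2 + 2 * k3_2 + k4_2);
    y3 += dt / 6.0 * (k1_3 + 2 * k2_3 + 2 * k3_3 + k4_3);
    if (!R_finite(y2)) stop("non-finite state at step %d during integration", k + 1);
    out[k + 1] = y2;
  }
  return out;
}

// One second-order LTI stage advanced by its exact first-order-hold
// discretisation: x[k+1] = Ad x[k] + B0 u[k] + B1 u[k+1]. The matrices are
// precomputed per segment of constant coefficients (distinct potentiation
// values); seg[k] (0-based) selects the matrices used for the step k -> k+1.
// Ad is nseg x 4 (column-major 2x2), B0/B1 are nseg x 2. Returns the first
// state component sampled on the grid.
// [[Rcpp::export]]
NumericVector cpp_lti2_foh(NumericVector u, IntegerVector seg,
                           NumericMatrix Ad, NumericMatrix B0,
                           NumericMatrix B1) {
  int n = u.size();
  NumericVector out(n);
  double x0 = 0, x1 = 0;
  out[0] = 0.0;
  for (int k = 0; k < n - 1; ++k) {
    int s = seg[k];
    double a11 = Ad(s, 0), a21 = Ad(s, 1), a12 = Ad(s, 2), a22 = Ad(s, 3);
    double n0 = a11 * x0 + a12 * x1 + B0(s, 0) * u[k] + B1(s, 0) * u[k + 1];
    double n1 = a21 * x0 + a22 * x1 + B0(s, 1) * u[k] + B1(s, 1) * u[k + 1];
    x0 = n0; x1 = n1;
    out[k + 1] = x0;
  }
  return out;
}

// Non-linear Wilson model: dCN/dt = u - CN/tau_c, x = CN^m/(CN^m + k^m),
// dF/dt = A x - F/(tau1 + tau2 x).
// [[Rcpp::export]]
NumericVector cpp_rk4_wilson_nl(NumericVector u, double tau_c, double tau1,
                                double tau2, double kk, double A, double m,
                                double dt) {
  int n = u.size();
  NumericVector out(n);
  double km = std::pow(kk, m);
  double cn = 0, F = 0;
  out[0] = 0.0;
  for (int k = 0; k < n - 1; ++k) {
    double u0 = u[k], u1 = u[k + 1], um = 0.5 * (u0 + u1);
    double k1c, k1f, k2c, k2f, k3c, k3f, k4c, k4f, cm, x;
    cm = std::pow(cn > 0 ? cn : 0.0, m); x = cm / (cm + km);
    k1c = u0 - cn / tau_c; k1f = A * x - F / (tau1 + tau2 * x);
    double tc = cn + 0.5 * dt * k1c, tf = F + 0.5 * dt * k1f;
    cm = std::pow(tc > 0 ? tc : 0.0, m); x = cm / (cm + km);
    k2c = um - tc / tau_c; k2f = A * x - tf / (tau1 + tau2 * x);
    tc = cn + 0.5 * dt * k2c; tf = F + 0.5 * dt * k2f;
    cm = std::pow(tc > 0 ? tc : 0.0, m); x = cm / (cm + km);
    k3c = um - tc / tau_c; k3f = A * x - tf / (tau1 + tau2 * x);
    tc = cn + dt * k3c; tf = F + dt * k3f;
    cm = std::pow(tc > 0 ? tc : 0.0, m); x = cm / (cm + km);
    k4c = u1 - tc / tau_c; k4f = A * x - tf / (tau1 + tau2 * x);
    cn += dt / 6.0 * (k1c + 2 * k2c + 2 * k3c + k4c);
    F += dt / 6.0 * (k1f + 2 * k2f + 2 * k3f + k4f);
    if (!R_finite(F)) stop("non-finite state at step %d during integration", k + 1);
    out[k + 1] = F;
  }
  return out;
}

// Third-order linear model th3 a''' + th2 a'' + th1 a' + a = th0 u, solved as
// a companion system of three first-order equations.
// [[Rcpp::export]]
NumericVector cpp_rk4_linear3(NumericVector u, double th0, double th1,
                              double th2, double th3, double dt) {
  int n = u.size();
  NumericVector out(n);
  double y0 = 0, y1 = 0, y2 = 0; // a, a', a''
  out[0] = 0.0;
  for (int k = 0; k < n - 1; ++k) {
    double u0 = u[k], u1 = u[k + 1], um = 0.5 * (u0 + u1);
    double k1_0 = y1, k1_1 = y2, k1_2 = (th0 * u0 - y0 - th1 * y1 - th2 * y2) / th3;
    double t0 = y0 + 0.5 * dt * k1_0, t1 = y1 + 0.5 * dt * k1_1, t2 = y2 + 0.5 * dt * k1_2;
    double k2_0 = t1, k2_1 = t2, k2_2 = (th0 * um - t0 - th1 * t1 - th2 * t2) / th3;
    t0 = y0 + 0.5 * dt * k2_0; t1 = y1 + 0.5 * dt * k2_1; t2 = y2 + 0.5 * dt * k2_2;
    double k3_0 = t1, k3_1 = t2, k3_2 = (th0 * um - t0 - th1 * t1 - th2 * t2) / th3;
    t0 = y0 + dt * k3_0; t1 = y1 + dt * k3_1; t2 = y2 + dt * k3_2;
    double k4_0 = t1, k4_1 = t2, k4_2 = (th0 * u1 - t0 - th1 * t1 - th2 * t2) / th3;
    y0 += dt / 6.0 * (k1_0 + 2 * k2_0 + 2 * k3_0 + k4_0);
    y1 += dt / 6.0 * (k1_1 + 2 * k2_1 + 2 * k3_1 + k4_1);
    y2 += dt / 6.0 * (k1_2 + 2 * k2_2 + 2 * k3_2 + k4_2);
    if (!R_finite(y0)) stop("non-finite state at step %d during integration", k + 1);
    out[k + 1] = y0;
  }
  return out;
}

// Zajac bilinear first-order model, advanced by the exact integrating-factor
// update with the excitation held at its mid-step value: the equation is
// scalar linear within a step, so the update is unconditionally stable.
// [[Rcpp::export]]
NumericVector cpp_zajac(NumericVector u, double tau_act, double beta,
                        double dt) {
  int n = u.size();
  NumericVector out(n);
  double a = 0;
  out[0] = 0.0;
  for (int k = 0; k < n - 1; ++k) {
    double um = 0.5 * (u[k] + u[k + 1]);
    double r = (beta + (1.0 - beta) * um) / tau_act; // always >= beta/tau_act > 0
    double drive = um / tau_act;
    double e = std::exp(-r * dt);
    a = a * e + drive / r * (1.0 - e);
    out[k + 1] = a;
  }
  return out;
}

// Bluemel single-pole recursive filter: a[n] = (1-filter) scaling u[n] + filter a[n-1].
// [[Rcpp::export]]
NumericVector cpp_blumel(NumericVector u, double filter, double scaling) {
  int n = u.size();
  NumericVector out(n);
  double a = 0;
  for (int k = 0; k < n; ++k) {
    a = (1.0 - filter) * (scaling * u[k]) + filter * a;
    out[k] = a;
  }
  return out;
}
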