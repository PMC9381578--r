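// Adaptive Dormand-Prince 5(4) integrator specialized to the photophilic
// strain circuit (T7 monomer D, active dimer A, CAT C, intracellular
// chloramphenicol c_in) optionally coupled to the co-culture composition
// phi_p. The growth rate is an algebraic function of state (quasi-steady
// proteome adaptation), so it is recomputed at every derivative evaluation.
//
// Parameter vector layout (see R/photophilic.R):
//  p[0] beta_T7   p[1] ka_dark  p[2] ka_light p[3] K_L   p[4] k_off
//  p[5] beta_CAT  p[6] n_T7     p[7] n_CAT    p[8] k_perm p[9] k_cat
//  p[10] K_M      p[11] i50
// Host vector: h[0] phi_R_max, h[1] phi_R0, h[2] gamma0, h[3] rho_cell

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct StrainSys {
  double p[12];
  double phi_R_max, phi_R0, gamma0, rho_cell;
  double nu, c_ext, lambda_c;
  bool with_phi;
  bool burden_error;

  double lambda_of(const double* y) {
    double phiS = (p[6] * (y[0] + 2.0 * y[1]) + p[7] * y[2]) / rho_cell;
    double room = phi_R_max - phi_R0;
    if (phiS > room) { burden_error = true; return 0.0; }
    double gamma = gamma0 / (1.0 + y[3] / p[11]);
    return (room - phiS) * gamma * nu / (gamma + nu);
  }

  void rhs(const double* y_in, double L, double* dy, double* lambda_out) {
    double y[5];
    int n = with_phi ? 5 : 4;
    for (int i = 0; i < n; ++i) y[i] = y_in[i] > 0.0 ? y_in[i] : 0.0;
    double lambda = lambda_of(y);
    double ka = p[1] + p[2] * L / (p[3] + L);
    dy[0] = p[0] * lambda * lambda / nu - 2.0 * ka * y[0] * y[0]
            + 2.0 * p[4] * y[1] - lambda * y[0];
    dy[1] = ka * y[0] * y[0] - p[4] * y[1] - lambda * y[1];
    dy[2] = p[5] * y[1] * lambda - lambda * y[2];
    dy[3] = p[8] * (c_ext - y[3]) - p[9] * y[2] * y[3] / (p[10] + y[3])
            - lambda * y[3];
    if (with_phi) {
      double phi = y[4] < 0.0 ? 0.0 : (y[4] > 1.0 ? 1.0 : y[4]);
      dy[4] = (lambda - lambda_c) * (1.0 - phi) * phi;
    }
    if (lambda_out) *lambda_out = lambda;
  }
};

// Dormand-Prince coefficients
static const double C2 = 1.0 / 5, C3 = 3.0 / 10, C4 = 4.0 / 5, C5 = 8.0 / 9;
static const double A21 = 1.0 / 5;
static const double A31 = 3.0 / 40, A32 = 9.0 / 40;
static const double A41 = 44.0 / 45, A42 = -56.0 / 15, A43 = 32.0 / 9;
static const double A51 = 19372.0 / 6561, A52 = -25360.0 / 2187,
                    A53 = 64448.0 / 6561, A54 = -212.0 / 729;
static const double A61 = 9017.0 / 3168, A62 = -355.0 / 33,
                    A63 = 46732.0 / 5247, A64 = 49.0 / 176,
                    A65 = -5103.0 / 18656;
static const double B1 = 35.0 / 384, B3 = 500.0 / 1113, B4 = 125.0 / 192,
                    B5 = -2187.0 / 6784, B6 = 11.0 / 84;
static const double E1 = 71.0 / 57600, E3 = -71.0 / 16695, E4 = 71.0 / 1920,
                    E5 = -17253.0 / 339200, E6 = 22.0 / 525, E7 = -1.0 / 40;

// Integrate y over [t0, t1] at constant light L, writing dense output into
// out(row, .) for requested times in (t0, t1]. Returns false on failure.
static bool integrate_segment(StrainSys& sys, double* y, int n,
                              double t0, double t1, double L,
                              const NumericVector& t_out, int& next_out,
                              NumericMatrix& out, NumericVector& lam_out,
                              double rtol, double atol) {
  double k1[5], k2[5], k3[5], k4[5], k5[5], k6[5], k7[5];
  double y2[5], y3[5], y4[5], y5[5], y6[5], ynew[5], yi[5];
  sys.rhs(y, L, k1, nullptr);
  if (sys.burden_error) return false;
  double t = t0;
  double h = std::min(1e-3, t1 - t0);
  int max_steps = 2000000;
  for (int step = 0; step < max_steps && t < t1; ++step) {
    if (h > t1 - t) h = t1 - t;
    double err;
    for (;;) {
      for (int i = 0; i < n; ++i) y2[i] = y[i] + h * A21 * k1[i];
      sys.rhs(y2, L, k2, nullptr);
      for (int i = 0; i < n; ++i) y3[i] = y[i] + h * (A31 * k1[i] + A32 * k2[i]);
      sys.rhs(y3, L, k3, nullptr);
      for (int i = 0; i < n; ++i)
        y4[i] = y[i] + h * (A41 * k1[i] + A42 * k2[i] + A43 * k3[i]);
      sys.rhs(y4, L, k4, nullptr);
      for (int i = 0; i < n; ++i)
        y5[i] = y[i] + h * (A51 * k1[i] + A52 * k2[i] + A53 * k3[i] + A54 * k4[i]);
      sys.rhs(y5, L, k5, nullptr);
      for (int i = 0; i < n; ++i)
        y6[i] = y[i] + h * (A61 * k1[i] + A62 * k2[i] + A63 * k3[i]
                            + A64 * k4[i] + A65 * k5[i]);
      sys.rhs(y6, L, k6, nullptr);
      for (int i = 0; i < n; ++i)
        ynew[i] = y[i] + h * (B1 * k1[i] + B3 * k3[i] + B4 * k4[i]
                              + B5 * k5[i] + B6 * k6[i]);
      sys.rhs(ynew, L, k7, nullptr);
      if (sys.burden_error) return false;
      double s = 0.0;
      for (int i = 0; i < n; ++i) {
        double ev = h * (E1 * k1[i] + E3 * k3[i] + E4 * k4[i] + E5 * k5[i]
                         + E6 * k6[i] + E7 * k7[i]);
        double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
        double r = ev / sc;
        s += r * r;
      }
      err = std::sqrt(s / n);
      if (!std::isfinite(err)) err = 2.0;
      if (err <= 1.0) break;
      double fac = 0.9 * std::pow(err, -0.2);
      h *= fac < 0.2 ? 0.2 : fac;
      if (h < 1e-14 * std::max(1.0, std::fabs(t))) return false;
    }
    double t_new = t + h;
    for (int i = 0; i < n; ++i) {
      if (ynew[i] < -1e-6) return false;   // excursion beyond solver tolerance
      if (ynew[i] < 0.0) ynew[i] = 0.0;
    }
    while (next_out < t_out.size() && t_out[next_out] <= t_new + 1e-14) {
      double s = (t_out[next_out] - t) / h;
      double h00 = (1 + 2 * s) * (1 - s) * (1 - s);
      double h10 = s * (1 - s) * (1 - s);
      double h01 = s * s * (3 - 2 * s);
      double h11 = s * s * (s - 1);
      for (int i = 0; i < n; ++i) {
        yi[i] = h00 * y[i] + h10 * h * k1[i] + h01 * ynew[i] + h11 * h * k7[i];
        if (yi[i] < 0.0) yi[i] = 0.0;
        out(next_out, i) = yi[i];
      }
      lam_out[next_out] = sys.lambda_of(yi);
      ++next_out;
    }
    for (int i = 0; i < n; ++i) { y[i] = ynew[i]; k1[i] = k7[i]; }
    t = t_new;
    double fac = 0.9 * std::pow(err, -0.2);
    if (fac > 5.0) fac = 5.0;
    if (fac < 0.2) fac = 0.2;
    h *= fac;
  }
  return t >= t1 - 1e-12;
}

// [[Rcpp::export]]
List cpp_simulate_strain(NumericVector y0, NumericVector seg_start,
                         NumericVector seg_end, NumericVector seg_light,
                         NumericVector t_out, NumericVector params,
                         NumericVector hostv, double nu, double c_ext,
                         double lambda_c, bool with_phi,
                         double rtol, double atol) {
  StrainSys sys;
  for (int i = 0; i < 12; ++i) sys.p[i] = params[i];
  sys.phi_R_max = hostv[0]; sys.phi_R0 = hostv[1];
  sys.gamma0 = hostv[2]; sys.rho_cell = hostv[3];
  sys.nu = nu; sys.c_ext = c_ext; sys.lambda_c = lambda_c;
  sys.with_phi = with_phi;
  sys.burden_error = false;
  int n = with_phi ? 5 : 4;
  if (y0.size() != n) stop("cpp_simulate_strain: state length mismatch");
  double y[5];
  for (int i = 0; i < n; ++i) y[i] = y0[i];
  NumericMatrix out(t_out.size(), n);
  NumericVector lam(t_out.size());
  int next_out = 0;
  // output at the very first time if it coincides with the start
  if (t_out.size() > 0 && t_out[0] <= seg_start[0] + 1e-14) {
    for (int i = 0; i < n; ++i) out(0, i) = y[i];
    lam[0] = sys.lambda_of(y);
    next_out = 1;
  }
  for (int s = 0; s < seg_start.size(); ++s) {
    bool ok = integrate_segment(sys, y, n, seg_start[s], seg_end[s],
                                seg_light[s], t_out, next_out, out, lam,
                                rtol, atol);
    if (!ok) {
      if (sys.burden_error)
        stop("strain integration failed: infeasible gene-expression burden");
      return List::create(_["ok"] = false, _["fail_t"] = seg_start[s]);
    }
  }
  // terminal state (may not be an output point)
  NumericVector yT(n);
  for (int i = 0; i < n; ++i) yT[i] = y[i];
  return List::create(_["ok"] = true, _["y"] = out, _["lambda"] = lam,
                      _["y_end"] = yT, _["lambda_end"] = sys.lambda_of(y));
}
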