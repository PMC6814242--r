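#include <Rcpp.h>
using namespace Rcpp;

// 5-point Laplacian with periodic wrap on the full lattice.
static inline double lap5(const NumericMatrix& X, int i, int j,
                          int up, int dn, int lf, int rt) {
  return X(up, j) + X(dn, j) + X(i, lf) + X(i, rt) - 4.0 * X(i, j);
}

// Activator-inhibitor stepper. Production only inside the colony mask,
// degradation everywhere (kd_out outside, species-specific rates inside),
// diffusion everywhere. Concentrations are clamped at zero after each step.
// The inhibitor in the activator production denominator is floored at
// i_floor so that edge-seeded initial conditions with I = 0 stay finite.
// [[Rcpp::export]]
List rd_run_cpp(NumericMatrix A0, NumericMatrix I0, LogicalMatrix mask,
                List params, double dt, int n_steps) {
  const int H = A0.nrow(), W = A0.ncol();
  const double D_A = params["D_A"], D_I = params["D_I"];
  const double s_A = params["s_A"], s_I = params["s_I"];
  const double k_I = params["k_I"], k_A = params["k_A"];
  const double kd_A = params["kd_A"], kd_I = params["kd_I"];
  const double kappa_A = params["kappa_A"], kd_out = params["kd_out"];
  const double i_floor = params["i_floor"];

  NumericMatrix A = clone(A0), I = clone(I0);
  NumericMatrix An(H, W), In(H, W);
  double max_rel_change = R_PosInf;
  bool bad = false;
  int steps_done = 0;

  for (int s = 0; s < n_steps; ++s) {
    double dmax = 0.0, fmax = 0.0;
    for (int j = 0; j < W; ++j) {
      const int lf = (j == 0) ? W - 1 : j - 1;
      const int rt = (j == W - 1) ? 0 : j + 1;
      for (int i = 0; i < H; ++i) {
        const int up = (i == 0) ? H - 1 : i - 1;
        const int dn = (i == H - 1) ? 0 : i + 1;
        const double a = A(i, j), ii = I(i, j);
        double pa = 0.0, pi = 0.0, ka = kd_out, ki = kd_out;
        if (mask(i, j)) {
          const double denom = k_I * std::max(ii, i_floor) *
            (1.0 + kappa_A * a * a);
          pa = s_A * a * a / denom + k_A;
          pi = s_I * a * a;
          ka = kd_A;
          ki = kd_I;
        }
        double an = a + dt * (D_A * lap5(A, i, j, up, dn, lf, rt) + pa - ka * a);
        double in = ii + dt * (D_I * lap5(I, i, j, up, dn, lf, rt) + pi - ki * ii);
        if (an < 0.0) an = 0.0;
        if (in < 0.0) in = 0.0;
        An(i, j) = an;
        In(i, j) = in;
        const double d = std::max(std::fabs(an - a), std::fabs(in - ii));
        if (d > dmax) dmax = d;
        const double f = std::max(std::fabs(an), std::fabs(in));
        if (f > fmax) fmax = f;
      }
    }
    std::swap(A, An);
    std::swap(I, In);
    ++steps_done;
    if (!R_finite(fmax) || fmax > 1e12) { bad = true; break; }
    max_rel_change = dmax / std::max(fmax, 1e-12);
  }
  return List::create(_["A"] = A, _["I"] = I,
                      _["max_rel_change"] = max_rel_change,
                      _["steps_done"] = steps_done,
                      _["diverged"] = bad);
}

// WNT (u) / NODAL (v) cascade stepper with an imposed BMP field b held
// constant over the chunk. Production inside the mask only, first-order
// degradation everywhere, periodic boundaries. dx2 = (pixel size)^2 in um^2.
// [[Rcpp::export]]
List cascade_run_cpp(NumericMatrix u0, NumericMatrix v0, NumericMatrix b,
                     LogicalMatrix mask, List params, double dx2,
                     double dt, int n_steps) {
  const int H = u0.nrow(), W = u0.ncol();
  const double D_u = params["D_u"], D_v = params["D_v"];
  const double beta_u = params["beta_u"], alpha_b = params["alpha_b"];
  const double alpha_u = params["alpha_u"], K_u = params["K_u"];
  const double alpha_w = params["alpha_w"], alpha_v = params["alpha_v"];
  const double K_v = params["K_v"], v_th = params["v_th"];
  const double gamma_u = params["gamma_u"], gamma_v = params["gamma_v"];
  const double gamma_out_u = params["gamma_out_u"];
  const double gamma_out_v = params["gamma_out_v"];

  NumericMatrix u = clone(u0), v = clone(v0);
  NumericMatrix un(H, W), vn(H, W);
  bool bad = false;
  const double Du_eff = D_u / dx2, Dv_eff = D_v / dx2;

  for (int s = 0; s < n_steps && !bad; ++s) {
    double fmax = 0.0;
    for (int j = 0; j < W; ++j) {
      const int lf = (j == 0) ? W - 1 : j - 1;
      const int rt = (j == W - 1) ? 0 : j + 1;
      for (int i = 0; i < H; ++i) {
        const int up = (i == 0) ? H - 1 : i - 1;
        const int dn = (i == H - 1) ? 0 : i + 1;
        const double uu = u(i, j), vv = v(i, j);
        double pu = 0.0, pv = 0.0;
        double gu = gamma_out_u, gv = gamma_out_v;
        if (mask(i, j)) {
          pu = beta_u + alpha_b * b(i, j) +
            alpha_u * uu * uu / (K_u * K_u + uu * uu);
          pv = alpha_w * uu;
          if (vv >= v_th)
            pv += alpha_v * vv * vv / (K_v * K_v + vv * vv);
          gu = gamma_u;
          gv = gamma_v;
        }
        double nu = uu + dt * (Du_eff * lap5(u, i, j, up, dn, lf, rt) +
                               pu - gu * uu);
        double nv = vv + dt * (Dv_eff * lap5(v, i, j, up, dn, lf, rt) +
                               pv - gv * vv);
        if (nu < 0.0) nu = 0.0;
        if (nv < 0.0) nv = 0.0;
        un(i, j) = nu;
        vn(i, j) = nv;
        const double f = std::max(nu, nv);
        if (f > fmax) fmax = f;
      }
    }
    std::swap(u, un);
    std::swap(v, vn);
    if (!R_finite(fmax) || fmax > 1e12) bad = true;
  }
  return List::create(_["u"] = u, _["v"] = v, _["diverged"] = bad);
}
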