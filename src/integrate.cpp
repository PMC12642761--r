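// Dormand-Prince 5(4) integration of the graph biomarker cascade system.
//
// State layout: y = (Abeta[1..n], tau[1..n], N[1..n], C), length 3n+1.
// Dynamics (elementwise products on region vectors):
//   dAb/dt = -D_ab  L Ab + lam_ab  . Ab . (K_ab  - Ab)
//   dTa/dt = -D_tau L Ta + lam_ta_ab . Ab + lam_ta . Ta . (K_ta - Ta)
//   dN/dt  = -D_n   L N  + lam_n_ta . Ta + lam_n  . N  . (K_n  - N)
//   dC/dt  = lam_cn * (sum_v d_v N_v / sum_v d_v) + lam_c * C * (K_c - C)
// The degree-weighted mean falls back to the plain mean on an edgeless graph
// so that single-node reductions remain well defined.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct CascadeParams {
  double D_ab, D_ta, D_n;
  vec lam_ab, lam_ta, lam_n, lam_ta_ab, lam_n_ta;
  vec K_ab, K_ta, K_n;
  double lam_cn, lam_c, K_c;
};

inline vec cascade_rhs(const vec& y, const mat& L, const vec& deg,
                       double degsum, const CascadeParams& p) {
  const uword n = L.n_rows;
  vec ab = y.subvec(0, n - 1);
  vec ta = y.subvec(n, 2 * n - 1);
  vec nn = y.subvec(2 * n, 3 * n - 1);
  double C = y(3 * n);

  vec dab = -p.D_ab * (L * ab) + p.lam_ab % ab % (p.K_ab - ab);
  vec dta = -p.D_ta * (L * ta) + p.lam_ta_ab % ab + p.lam_ta % ta % (p.K_ta - ta);
  vec dnn = -p.D_n  * (L * nn) + p.lam_n_ta % ta + p.lam_n % nn % (p.K_n - nn);

  double nint = (degsum > 0.0) ? dot(deg, nn) / degsum : mean(nn);
  double dC = p.lam_cn * nint + p.lam_c * C * (p.K_c - C);

  vec dy(3 * n + 1);
  dy.subvec(0, n - 1) = dab;
  dy.subvec(n, 2 * n - 1) = dta;
  dy.subvec(2 * n, 3 * n - 1) = dnn;
  dy(3 * n) = dC;
  return dy;
}

}  // namespace

// Integrate from t0 with state y0, returning the state at each requested time.
// times must be nondecreasing with times[0] >= t0.  Classic embedded DP5(4)
// pair with PI-free step control; steps are clipped to land exactly on each
// output time, so no dense-output interpolant is needed.
// [[Rcpp::export(name = ".adbc_integrate_cpp")]]
arma::mat adbc_integrate_cpp(const arma::vec& times, double t0,
                             const arma::vec& y0, const arma::mat& L,
                             const Rcpp::List& params, double rtol,
                             double atol, int max_steps) {
  const uword n = L.n_rows;
  if (y0.n_elem != 3 * n + 1)
    Rcpp::stop("state length must be 3*n+1 for an n-region graph");

  CascadeParams p;
  p.D_ab = Rcpp::as<double>(params["D_Abeta"]);
  p.D_ta = Rcpp::as<double>(params["D_tau"]);
  p.D_n  = Rcpp::as<double>(params["D_N"]);
  p.lam_ab = Rcpp::as<vec>(params["lambda_Abeta"]);
  p.lam_ta = Rcpp::as<vec>(params["lambda_tau"]);
  p.lam_n  = Rcpp::as<vec>(params["lambda_N"]);
  p.lam_ta_ab = Rcpp::as<vec>(params["lambda_tauAbeta"]);
  p.lam_n_ta  = Rcpp::as<vec>(params["lambda_Ntau"]);
  p.K_ab = Rcpp::as<vec>(params["K_Abeta"]);
  p.K_ta = Rcpp::as<vec>(params["K_tau"]);
  p.K_n  = Rcpp::as<vec>(params["K_N"]);
  p.lam_cn = Rcpp::as<double>(params["lambda_CN"]);
  p.lam_c  = Rcpp::as<double>(params["lambda_C"]);
  p.K_c    = Rcpp::as<double>(params["K_C"]);

  // degree of the underlying adjacency: L = D - A has zero row sums, so
  // d_i = L_ii.
  vec deg = L.diag();
  double degsum = accu(deg);

  // Dormand-Prince coefficients.
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
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
  // 4th-order embedded weights.
  static const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695,
                      e4 = 393.0 / 640, e5 = -92097.0 / 339200,
                      e6 = 187.0 / 2100, e7 = 1.0 / 40;

  const uword m = times.n_elem;
  mat out(3 * n + 1, m);

  double t = t0;
  vec y = y0;
  vec k1 = cascade_rhs(y, L, deg, degsum, p);  // FSAL
  double tend = times(m - 1);
  double h = std::min(1.0, std::max(1e-6, (tend - t0) / 10.0));
  uword next_out = 0;
  int steps = 0;

  // Emit any output times at (or numerically before) t0.
  while (next_out < m && times(next_out) <= t + 1e-12) {
    out.col(next_out) = y;
    ++next_out;
  }

  while (next_out < m) {
    if (++steps > max_steps)
      Rcpp::stop("cascade integration exceeded %d steps (t=%g, h=%g)",
                 max_steps, t, h);
    bool hit_output = false;
    double h_free = h;  // unclipped step, basis for the next step size
    double t_target = times(next_out);
    if (t + h >= t_target - 1e-12) {
      h = t_target - t;
      hit_output = true;
    }

    vec k2 = cascade_rhs(y + h * a21 * k1, L, deg, degsum, p);
    vec k3 = cascade_rhs(y + h * (a31 * k1 + a32 * k2), L, deg, degsum, p);
    vec k4 = cascade_rhs(y + h * (a41 * k1 + a42 * k2 + a43 * k3), L, deg, degsum, p);
    vec k5 = cascade_rhs(y + h * (a51 * k1 + a52 * k2 + a53 * k3 + a54 * k4),
                         L, deg, degsum, p);
    vec k6 = cascade_rhs(y + h * (a61 * k1 + a62 * k2 + a63 * k3 + a64 * k4 +
                                  a65 * k5), L, deg, degsum, p);
    vec y5 = y + h * (b1 * k1 + b3 * k3 + b4 * k4 + b5 * k5 + b6 * k6);
    vec k7 = cascade_rhs(y5, L, deg, degsum, p);
    vec y4 = y + h * (e1 * k1 + e3 * k3 + e4 * k4 + e5 * k5 + e6 * k6 + e7 * k7);

    vec sc = atol + rtol * max(abs(y), abs(y5));
    double err = std::sqrt(accu(square((y5 - y4) / sc)) / (3 * n + 1));

    if (!std::isfinite(err)) {
      h *= 0.25;
      if (h < 1e-12)
        Rcpp::stop("cascade integration step underflow (non-finite state)");
      continue;
    }

    if (err <= 1.0) {
      t += h;
      y = y5;
      k1 = k7;
      if (hit_output) {
        out.col(next_out) = y;
        ++next_out;
        // collapse duplicated output times
        while (next_out < m && times(next_out) <= t + 1e-12) {
          out.col(next_out) = y;
          ++next_out;
        }
      }
      double fac = (err > 0) ? 0.9 * std::pow(err, -0.2) : 5.0;
      h = h_free * std::min(5.0, std::max(0.2, fac));
    } else {
      h *= std::max(0.1, 0.9 * std::pow(err, -0.2));
    }
    if (h < 1e-12)
      Rcpp::stop("cascade integration step underflow at t=%g", t);
    double remaining = tend - t;
    if (h > remaining && remaining > 0) h = remaining;
  }

  return out;
}
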