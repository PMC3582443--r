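#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Rodrigues rotation: R <- exp([w]x) * R, w a rotation vector in the lab frame.
static void apply_rotation(double R[3][3], const double w[3]) {
  double th = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
  if (th < 1e-300) return;
  double k[3] = {w[0] / th, w[1] / th, w[2] / th};
  double c = std::cos(th), s = std::sin(th), v = 1.0 - c;
  double Q[3][3] = {
    {c + k[0] * k[0] * v,        k[0] * k[1] * v - k[2] * s, k[0] * k[2] * v + k[1] * s},
    {k[1] * k[0] * v + k[2] * s, c + k[1] * k[1] * v,        k[1] * k[2] * v - k[0] * s},
    {k[2] * k[0] * v - k[1] * s, k[2] * k[1] * v + k[0] * s, c + k[2] * k[2] * v}
  };
  double out[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      out[i][j] = Q[i][0] * R[0][j] + Q[i][1] * R[1][j] + Q[i][2] * R[2][j];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      R[i][j] = out[i][j];
}

// Euler-scheme rotational Brownian dynamics in a uniaxial orienting
// potential U/kT = -lambda * cos^2(beta) about the lab z-axis.
// Noise: lab-frame rotation vector with iid N(0, 2*D*dt) components.
// Drift: rotation of the body z-axis toward the nearer pole by
// D*lambda*sin(2*beta)*dt about the axis z_body x z_lab.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector rotbd_simulate_cpp(int n_steps, double D_dt, double lambda,
                                 NumericMatrix R0) {
  NumericVector out(Dimension(3, 3, n_steps));
  double R[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      R[i][j] = R0(i, j);
  double sig = std::sqrt(2.0 * D_dt);
  RNGScope scope;
  for (int t = 0; t < n_steps; ++t) {
    double w[3] = {R::norm_rand() * sig, R::norm_rand() * sig,
                   R::norm_rand() * sig};
    apply_rotation(R, w);
    if (lambda != 0.0) {
      // body z-axis in the lab frame is the third column of R
      double zx = R[0][2], zy = R[1][2], zz = R[2][2];
      // axis a = z_body x z_lab = (zy, -zx, 0); rotation by +delta about a
      // moves z_body toward +z_lab
      double sperp = std::sqrt(zx * zx + zy * zy);
      if (sperp > 1e-12) {
        double sin2b = 2.0 * sperp * zz;  // sin(beta) >= 0 by construction
        double delta = D_dt * lambda * sin2b;
        double a[3] = {zy / sperp * delta, -zx / sperp * delta, 0.0};
        apply_rotation(R, a);
      }
    }
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        out[9 * t + 3 * j + i] = R[i][j];
  }
  return out;
}
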