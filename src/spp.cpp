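#include <Rcpp.h>
using namespace Rcpp;

// Wall-avoidance turning angle: forward impact point of the heading ray on
// the arena circle, phi = angle between heading and the outward boundary
// normal there (phi in [0, pi/2) for a forward impact), theta = v0*phi/d
// capped at pi/2, signed to rotate toward the inward normal.
static inline double wall_theta(double px, double py, double hx, double hy,
                                double v0, double R) {
  double b = px * hx + py * hy;
  double disc = b * b + R * R - (px * px + py * py);
  if (disc < 0) disc = 0;
  double d = -b + std::sqrt(disc);
  double ix = px + d * hx, iy = py + d * hy;
  double nx = ix / R, ny = iy / R;
  double c = hx * nx + hy * ny;
  if (c > 1) c = 1;
  if (c < -1) c = -1;
  double phi = std::acos(c);
  double theta = (d > 1e-12) ? v0 * phi / d : M_PI / 2.0;
  if (theta > M_PI / 2.0) theta = M_PI / 2.0;
  double cr = -(hx * ny - hy * nx); // cross(heading, inward normal)
  return (cr >= 0) ? theta : -theta;
}

// Synchronous iteration of the self-propelled particle model. Consumes one
// standard normal variate per particle per step from R's RNG, in particle
// order, exactly like the R reference step.
// [[Rcpp::export]]
List cpp_spp_run(NumericVector x0, NumericVector y0,
                 NumericVector vx0, NumericVector vy0, NumericVector h0,
                 double R, double zor, double zoa,
                 double v0, double gamma, double eta, double dt,
                 int n_steps, int burn_in, bool reflect) {
  RNGScope scope;
  const int n = x0.size();
  const double zor2 = zor * zor, zoa2 = zoa * zoa, R2 = R * R;
  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end());
  std::vector<double> vx(vx0.begin(), vx0.end()), vy(vy0.begin(), vy0.end());
  std::vector<double> h(h0.begin(), h0.end());
  std::vector<double> nx_(n), ny_(n), nvx(n), nvy(n), nh(n);

  const int n_keep = n_steps - burn_in;
  NumericMatrix X(n_keep, n), Y(n_keep, n), VX(n_keep, n), VY(n_keep, n),
      H(n_keep, n);

  for (int t = 1; t <= n_steps; ++t) {
    for (int i = 0; i < n; ++i) {
      double sx = 0, sy = 0;
      bool rep = false;
      double ax = 0, ay = 0, cx = 0, cy = 0;
      int na = 0;
      for (int j = 0; j < n; ++j) {
        double dx = x[j] - x[i], dy = y[j] - y[i];
        double d2 = dx * dx + dy * dy;
        if (j != i && d2 < zor2) {
          rep = true;
          sx += dx;
          sy += dy;
        }
        if (d2 <= zoa2) {
          ax += vx[j];
          ay += vy[j];
          cx += std::cos(h[j]);
          cy += std::sin(h[j]);
          ++na;
        }
      }
      double ux, uy;
      if (rep) {
        double m = std::sqrt(sx * sx + sy * sy);
        if (m > 0) {
          ux = -sx / m;
          uy = -sy / m;
        } else {
          ux = std::cos(h[i]);
          uy = std::sin(h[i]);
        }
      } else {
        double m = std::sqrt(ax * ax + ay * ay);
        if (m > 0) {
          ux = ax / m;
          uy = ay / m;
        } else {
          ux = std::cos(h[i]);
          uy = std::sin(h[i]);
        }
      }
      double psi = std::sqrt(cx * cx + cy * cy) / na;
      if (psi > 1) psi = 1;
      double sp = v0 * std::pow(psi, gamma);
      double ang = std::atan2(uy, ux) + norm_rand() * eta;
      ang += wall_theta(x[i], y[i], std::cos(ang), std::sin(ang), v0, R);
      double vxi = sp * std::cos(ang), vyi = sp * std::sin(ang);
      double px = x[i] + vxi * dt, py = y[i] + vyi * dt;
      if (px * px + py * py > R2) {
        if (reflect) {
          double ddx = px - x[i], ddy = py - y[i];
          double A = ddx * ddx + ddy * ddy;
          double B = x[i] * ddx + y[i] * ddy;
          double C = x[i] * x[i] + y[i] * y[i] - R2;
          double q = B * B - A * C;
          if (q < 0) q = 0;
          double tc = (-B + std::sqrt(q)) / A;
          double cxp = x[i] + tc * ddx, cyp = y[i] + tc * ddy;
          double nxu = cxp / R, nyu = cyp / R;
          double rx = (1 - tc) * ddx, ry = (1 - tc) * ddy;
          double dot = rx * nxu + ry * nyu;
          rx -= 2 * dot * nxu;
          ry -= 2 * dot * nyu;
          px = cxp + rx;
          py = cyp + ry;
          double vdot = vxi * nxu + vyi * nyu;
          vxi -= 2 * vdot * nxu;
          vyi -= 2 * vdot * nyu;
          if (sp > 0) ang = std::atan2(vyi, vxi);
          double m2 = px * px + py * py;
          if (m2 > R2) {
            double m = std::sqrt(m2);
            px *= R / m;
            py *= R / m;
          }
        } else {
          double m = std::sqrt(px * px + py * py);
          px *= R / m;
          py *= R / m;
        }
      }
      nx_[i] = px;
      ny_[i] = py;
      nvx[i] = vxi;
      nvy[i] = vyi;
      nh[i] = ang;
    }
    x = nx_;
    y = ny_;
    vx = nvx;
    vy = nvy;
    h = nh;
    if (t > burn_in) {
      int r = t - burn_in - 1;
      for (int i = 0; i < n; ++i) {
        X(r, i) = x[i];
        Y(r, i) = y[i];
        VX(r, i) = vx[i];
        VY(r, i) = vy[i];
        H(r, i) = h[i];
      }
    }
  }
  return List::create(_["x"] = X, _["y"] = Y, _["vx"] = VX, _["vy"] = VY,
                      _["heading"] = H);
}
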