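// Stokes-drag particle tracer on a gridded velocity field.
//
// Positions are in micrometres, velocities in m/s, times in seconds.
// The drag ODE  dv/dt = (u(x) - v)/tau  with tau = rho_p Dp^2 / (18 mu)
// is stiff at micron scales (tau ~ 1e-7..1e-5 s against ~0.1 s transits),
// so the stiff mode is integrated exactly: per step the fluid velocity is
// frozen (then midpoint-corrected) and the exponential solution applied.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

namespace {

struct Grid {
  double gx0, gy0, h; // node origin and spacing, um
  const mat *u, *v;   // (nx+1) x (ny+1) node values, m/s
};

// bilinear interpolation of (u, v) at (x, y) um; clamps to the grid hull
inline void interp_uv(const Grid &g, double x, double y, double &ui, double &vi) {
  double fx = (x - g.gx0) / g.h, fy = (y - g.gy0) / g.h;
  int nx = g.u->n_rows - 1, ny = g.u->n_cols - 1;
  if (fx < 0) fx = 0; if (fx > nx - 1e-12) fx = nx - 1e-12;
  if (fy < 0) fy = 0; if (fy > ny - 1e-12) fy = ny - 1e-12;
  int i = (int)std::floor(fx), j = (int)std::floor(fy);
  double ax = fx - i, ay = fy - j;
  ui = (1 - ax) * (1 - ay) * (*g.u)(i, j) + ax * (1 - ay) * (*g.u)(i + 1, j)
     + (1 - ax) * ay * (*g.u)(i, j + 1) + ax * ay * (*g.u)(i + 1, j + 1);
  vi = (1 - ax) * (1 - ay) * (*g.v)(i, j) + ax * (1 - ay) * (*g.v)(i + 1, j)
     + (1 - ax) * ay * (*g.v)(i, j + 1) + ax * ay * (*g.v)(i + 1, j + 1);
}

// distance from point to segment (x1,y1)-(x2,y2)
inline double seg_dist(double px, double py, double x1, double y1, double x2, double y2) {
  double dx = x2 - x1, dy = y2 - y1;
  double L2 = dx * dx + dy * dy;
  double t = L2 > 0 ? ((px - x1) * dx + (py - y1) * dy) / L2 : 0.0;
  if (t < 0) t = 0; if (t > 1) t = 1;
  double ex = px - (x1 + t * dx), ey = py - (y1 + t * dy);
  return std::sqrt(ex * ex + ey * ey);
}

inline double wall_dist(const mat &walls, double x, double y) {
  double d = datum::inf;
  for (uword k = 0; k < walls.n_rows; ++k) {
    double dk = seg_dist(x, y, walls(k, 0), walls(k, 1), walls(k, 2), walls(k, 3));
    if (dk < d) d = dk;
  }
  return d;
}

// signed distance past a port plane: > 0 means beyond the opening
inline double port_excess(const rowvec &p, double x, double y) {
  return (x - p(0)) * p(4) + (y - p(1)) * p(5);
}
// lateral containment along the port segment (with slack um)
inline bool port_lateral_ok(const rowvec &p, double x, double y, double slack) {
  double dx = p(2) - p(0), dy = p(3) - p(1);
  double L = std::sqrt(dx * dx + dy * dy);
  double t = ((x - p(0)) * dx + (y - p(1)) * dy) / L;
  return t >= -slack && t <= L + slack;
}

} // namespace

// ports: nport x 6 matrix (x1,y1,x2,y2, nx_out, ny_out) in um / unit normal.
// walls: nseg x 4 matrix of wall segments, um.
// Returns t (s), x, y (um), status 0=EXITED 1=FROZEN 2=MAX_TIME, exit_port
// (1-based index into ports, 0 if none), and the particle velocity history.
// [[Rcpp::export]]
Rcpp::List trace_particle_cpp(const arma::mat &u, const arma::mat &v,
                              double gx0, double gy0, double h,
                              const arma::mat &walls, const arma::mat &ports,
                              double x0, double y0,
                              double dp_um, double rho_p, double mu,
                              double step_frac, double max_time, double u_ref,
                              bool from_rest) {
  Grid g{gx0, gy0, h, &u, &v};
  double rp = dp_um / 2.0;
  double tau = rho_p * (dp_um * 1e-6) * (dp_um * 1e-6) / (18.0 * mu);
  double u_floor = std::max(u_ref * 1e-6, 1e-12);

  std::vector<double> T, X, Y;
  double x = x0, y = y0, t = 0.0;
  double ux, uy; interp_uv(g, x, y, ux, uy);
  // default release at the local fluid velocity; from_rest exposes the
  // drag-relaxation transient
  double vx = from_rest ? 0.0 : ux, vy = from_rest ? 0.0 : uy;
  T.push_back(t); X.push_back(x); Y.push_back(y);

  int status = 2, exit_port = 0;
  const int max_steps = 2000000;

  for (int it = 0; it < max_steps; ++it) {
    if (t >= max_time) { status = 2; break; }
    double speed = std::sqrt(vx * vx + vy * vy);
    double u1x, u1y; interp_uv(g, x, y, u1x, u1y);
    double sp2 = std::sqrt(u1x * u1x + u1y * u1y);
    if (sp2 > speed) speed = sp2;
    double dt = step_frac * h * 1e-6 / std::max(speed, u_floor);
    if (dt > max_time / 8.0) dt = max_time / 8.0;
    if (t + dt > max_time) dt = max_time - t;
    double a = std::exp(-dt / tau);

    // predictor with frozen fluid velocity, then midpoint correction
    double xs = x + (u1x * dt + tau * (vx - u1x) * (1 - a)) * 1e6;
    double ys = y + (u1y * dt + tau * (vy - u1y) * (1 - a)) * 1e6;
    double u2x, u2y; interp_uv(g, xs, ys, u2x, u2y);
    double ubx = 0.5 * (u1x + u2x), uby = 0.5 * (u1y + u2y);
    double xn = x + (ubx * dt + tau * (vx - ubx) * (1 - a)) * 1e6;
    double yn = y + (uby * dt + tau * (vy - uby) * (1 - a)) * 1e6;
    double vnx = u2x + (vx - ubx) * a;
    double vny = u2y + (vy - uby) * a;
    double tn = t + dt;

    // port exit: interpolate to the crossing plane
    int hit = 0; double best_f = 2.0;
    for (uword k = 0; k < ports.n_rows; ++k) {
      double s1 = port_excess(ports.row(k), x, y);
      double s2 = port_excess(ports.row(k), xn, yn);
      if (s2 > 0 && s1 <= 0) {
        double f = s1 / (s1 - s2);
        double cx = x + f * (xn - x), cy = y + f * (yn - y);
        if (port_lateral_ok(ports.row(k), cx, cy, h) && f < best_f) {
          best_f = f; hit = (int)k + 1;
        }
      }
    }
    if (hit > 0) {
      double f = best_f;
      x = x + f * (xn - x); y = y + f * (yn - y); t = t + f * dt;
      T.push_back(t); X.push_back(x); Y.push_back(y);
      status = 0; exit_port = hit; break;
    }

    // wall contact (finite particle radius): bisect to the contact point
    double dn = wall_dist(walls, xn, yn);
    if (dn < rp) {
      double flo = 0.0, fhi = 1.0;
      for (int b = 0; b < 40; ++b) {
        double fm = 0.5 * (flo + fhi);
        double dm = wall_dist(walls, x + fm * (xn - x), y + fm * (yn - y));
        if (dm < rp) fhi = fm; else flo = fm;
      }
      x = x + fhi * (xn - x); y = y + fhi * (yn - y); t = t + fhi * dt;
      T.push_back(t); X.push_back(x); Y.push_back(y);
      status = 1; break;
    }

    x = xn; y = yn; t = tn; vx = vnx; vy = vny;
    T.push_back(t); X.push_back(x); Y.push_back(y);
  }

  return Rcpp::List::create(
    Rcpp::Named("t") = T, Rcpp::Named("x") = X, Rcpp::Named("y") = Y,
    Rcpp::Named("status") = status, Rcpp::Named("exit_port") = exit_port,
    Rcpp::Named("v_final") = Rcpp::NumericVector::create(vx, vy),
    Rcpp::Named("tau") = tau);
}

// [[Rcpp::export]]
double wall_distance_cpp(const arma::mat &walls, double x, double y) {
  return wall_dist(walls, x, y);
}
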