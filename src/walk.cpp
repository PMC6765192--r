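#include <Rcpp.h>
using namespace Rcpp;

// Sample a discrete-time Markov chain of length n_steps + 1 from cumulative
// row-transition probabilities (states 1..k), using pre-drawn uniforms so the
// caller owns the RNG stream.
// [[Rcpp::export(name = ".markov_chain")]]
IntegerVector markov_chain_cpp(int n_steps, int s0, NumericMatrix Pcum,
                               NumericVector u) {
  int k = Pcum.nrow();
  IntegerVector s(n_steps + 1);
  s[0] = s0;
  int cur = s0;
  for (int i = 0; i < n_steps; ++i) {
    double ui = u[i];
    int nxt = k;
    for (int j = 0; j < k; ++j) {
      if (ui <= Pcum(cur - 1, j)) { nxt = j + 1; break; }
    }
    cur = nxt;
    s[i + 1] = cur;
  }
  return s;
}

// Correlated random walk of one larva in a circular well split by a divider
// line through the centre (unit normal (nx, ny) pointing into the dark
// half; offset <= 0 is light). Per step: heading picks up a pre-drawn turn
// plus a wall-attraction steering term, the step length is speed * dt, a
// divider crossing is accepted with a side-dependent probability (rejected
// crossings reflect specularly off the divider), and wall hits reflect
// specularly with a radial fold back into the well.
// [[Rcpp::export(name = ".walk_engine")]]
List walk_engine_cpp(NumericVector speeds, NumericVector turns,
                     NumericVector cross_u, double x0, double y0,
                     double theta0, double cx, double cy, double R,
                     double nx, double ny, double wall_attraction,
                     double accept_light_to_dark, double accept_dark_to_light,
                     double dt) {
  int n = speeds.size();
  NumericVector x(n + 1), y(n + 1);
  IntegerVector dark(n + 1);
  x[0] = x0; y[0] = y0;
  double s0 = (x0 - cx) * nx + (y0 - cy) * ny;
  dark[0] = s0 > 0 ? 1 : 0;
  double theta = theta0;
  for (int i = 0; i < n; ++i) {
    double xi = x[i], yi = y[i];
    double rx = xi - cx, ry = yi - cy;
    double r = std::sqrt(rx * rx + ry * ry);
    if (wall_attraction > 0 && r > 1e-9) {
      double phi_out = std::atan2(ry, rx);
      theta += wall_attraction * std::sin(phi_out - theta) * dt;
    }
    theta += turns[i];
    double step = speeds[i] * dt;
    double px = xi + step * std::cos(theta);
    double py = yi + step * std::sin(theta);
    // divider crossing
    double si = (xi - cx) * nx + (yi - cy) * ny;
    double sp = (px - cx) * nx + (py - cy) * ny;
    bool from_dark = si > 0, to_dark = sp > 0;
    if (from_dark != to_dark) {
      double acc = from_dark ? accept_dark_to_light : accept_light_to_dark;
      if (cross_u[i] >= acc) {
        // reflect proposed point and heading across the divider line
        px -= 2.0 * sp * nx;
        py -= 2.0 * sp * ny;
        double dxh = std::cos(theta), dyh = std::sin(theta);
        double dn = dxh * nx + dyh * ny;
        theta = std::atan2(dyh - 2.0 * dn * ny, dxh - 2.0 * dn * nx);
      }
    }
    // wall reflection (radial fold; steps are far smaller than R)
    double prx = px - cx, pry = py - cy;
    double pr = std::sqrt(prx * prx + pry * pry);
    if (pr > R) {
      double rho = 2.0 * R - pr;
      if (rho < 0) rho = 0.999 * R;
      px = cx + prx * rho / pr;
      py = cy + pry * rho / pr;
      double phi = std::atan2(pry, prx);
      theta = 2.0 * (phi + M_PI / 2.0) - theta;
    }
    x[i + 1] = px; y[i + 1] = py;
    double sf = (px - cx) * nx + (py - cy) * ny;
    dark[i + 1] = sf > 0 ? 1 : 0;
  }
  return List::create(_["x"] = x, _["y"] = y, _["dark"] = dark,
                      _["theta"] = theta);
}
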