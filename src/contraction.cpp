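#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Tridiagonal (Thomas) solve; rows may be boundary rows. Overwrites inputs.
static void thomas(std::vector<double>& lo, std::vector<double>& di,
                   std::vector<double>& up, std::vector<double>& rhs,
                   std::vector<double>& v) {
  const int n = di.size();
  for (int i = 1; i < n; ++i) {
    double w = lo[i] / di[i - 1];
    di[i] -= w * up[i - 1];
    rhs[i] -= w * rhs[i - 1];
  }
  v[n - 1] = rhs[n - 1] / di[n - 1];
  for (int i = n - 2; i >= 0; --i)
    v[i] = (rhs[i] - up[i] * v[i + 1]) / di[i];
}

// Force balance eta v'' - gamma v = d sigma / dx on the current Lagrangian
// grid, with total-stress-free boundaries (eta dv/dx = sigma at both free
// edges).  sigma = s rho (rho - rho_pref) per cell.  When gamma == 0 the
// Neumann problem is singular up to a rigid translation; the solution is
// fixed by requiring zero net (mass-weighted) momentum, which keeps the
// centre of mass stationary.
static void force_balance(const std::vector<double>& x,
                          const std::vector<double>& rho,
                          double eta, double gamma, double s, double rho_pref,
                          std::vector<double>& v) {
  const int N = rho.size();      // cells
  const int n = N + 1;           // nodes
  std::vector<double> lo(n, 0.0), di(n, 0.0), up(n, 0.0), rhs(n, 0.0);
  std::vector<double> h(N), sig(N);
  for (int i = 0; i < N; ++i) {
    h[i] = x[i + 1] - x[i];
    if (!(h[i] > 0.0)) stop("degenerate grid: node positions must be strictly increasing");
    sig[i] = s * rho[i] * (rho[i] - rho_pref);
  }
  // boundary rows: eta (v1 - v0)/h0 = sig0 ; eta (vN - vN-1)/h(N-1) = sig(N-1)
  di[0] = -eta / h[0];      up[0] = eta / h[0];      rhs[0] = sig[0];
  di[n - 1] = eta / h[N - 1]; lo[n - 1] = -eta / h[N - 1]; rhs[n - 1] = sig[N - 1];
  for (int i = 1; i < n - 1; ++i) {
    double hl = h[i - 1], hr = h[i], hm = 0.5 * (hl + hr);
    lo[i] = eta / (hl * hm);
    di[i] = -eta * (1.0 / hl + 1.0 / hr) / hm - gamma;
    up[i] = eta / (hr * hm);
    rhs[i] = (sig[i] - sig[i - 1]) / hm;
  }
  if (gamma == 0.0) {
    // pin the node nearest the mass centroid, solve, then remove the
    // mass-weighted mean cell velocity
    double M = 0.0, xc = 0.0;
    for (int i = 0; i < N; ++i) {
      double m = rho[i] * h[i];
      M += m; xc += m * 0.5 * (x[i] + x[i + 1]);
    }
    xc /= M;
    int pin = 0; double best = std::abs(x[0] - xc);
    for (int i = 1; i < n; ++i) {
      double d = std::abs(x[i] - xc);
      if (d < best) { best = d; pin = i; }
    }
    lo[pin] = 0.0; di[pin] = 1.0; up[pin] = 0.0; rhs[pin] = 0.0;
    thomas(lo, di, up, rhs, v);
    double p = 0.0;
    for (int i = 0; i < N; ++i) p += rho[i] * h[i] * 0.5 * (v[i] + v[i + 1]);
    p /= M;
    for (int i = 0; i < n; ++i) v[i] -= p;
  } else {
    thomas(lo, di, up, rhs, v);
  }
}

// [[Rcpp::export]]
NumericVector fb_core(NumericVector x, NumericVector rho,
                      double eta, double gamma, double s, double rho_pref) {
  std::vector<double> xx(x.begin(), x.end()), rr(rho.begin(), rho.end());
  std::vector<double> v(x.size());
  force_balance(xx, rr, eta, gamma, s, rho_pref, v);
  return NumericVector(v.begin(), v.end());
}

// Time-steps the free-boundary system.  Heun (explicit trapezoidal) node
// advection with adaptive
// dt <= min(c1 * min_h / max|dv_adjacent|, c2 * eta/(s rho_pref^2)).
// Records snapshots either at the explicit sorted times `out_times`
// (eps_stop <= 0), or on the grid k * out_dt until the contracted fraction
// reaches eps_stop or time reaches t_cap.
// [[Rcpp::export]]
List simulate_core(NumericVector x0, NumericVector rho_init,
                   double eta, double gamma, double s, double rho_pref,
                   NumericVector out_times, double eps_stop, double out_dt,
                   double t_cap, double c1, double c2, int max_steps) {
  const int N = rho_init.size(), n = N + 1;
  std::vector<double> x(x0.begin(), x0.end()), rho(rho_init.begin(), rho_init.end());
  std::vector<double> mass(N), v(n), v2(n), xs(n), rs(N), h(N);
  for (int i = 0; i < N; ++i) mass[i] = rho[i] * (x[i + 1] - x[i]);
  const double W0 = x[N] - x[0];
  const double visc_time = eta / (s * rho_pref * rho_pref);
  const bool explicit_times = (eps_stop <= 0.0);
  const int n_exp = out_times.size();

  std::vector<double> rec_t;
  std::vector<std::vector<double>> rec_x, rec_rho, rec_v;
  bool converged = true;
  double t = 0.0;
  int k = 0, steps = 0;

  auto record = [&](void) {
    force_balance(x, rho, eta, gamma, s, rho_pref, v);
    rec_t.push_back(t); rec_x.push_back(x); rec_rho.push_back(rho); rec_v.push_back(v);
  };

  while (true) {
    double t_next;
    if (explicit_times) {
      if (k >= n_exp) break;
      t_next = out_times[k];
    } else {
      t_next = k * out_dt;
      if (t_next > t_cap) { converged = false; break; }
    }
    // integrate up to t_next
    while (t < t_next - 1e-12) {
      if (++steps > max_steps) stop("maximum step count exceeded before reaching requested time");
      force_balance(x, rho, eta, gamma, s, rho_pref, v);
      double min_h = R_PosInf, max_dv = 0.0;
      for (int i = 0; i < N; ++i) {
        double hi = x[i + 1] - x[i];
        if (hi < min_h) min_h = hi;
        double dv = std::abs(v[i + 1] - v[i]);
        if (dv > max_dv) max_dv = dv;
      }
      double dt = c2 * visc_time;
      if (max_dv > 0.0) dt = std::min(dt, c1 * min_h / max_dv);
      dt = std::min(dt, t_next - t);
      // Heun: predictor with v, corrector with the mean of v and the
      // velocity at the predicted state
      for (int i = 0; i < n; ++i) xs[i] = x[i] + dt * v[i];
      for (int i = 0; i < N; ++i) {
        double hi = xs[i + 1] - xs[i];
        if (!(hi > 0.0))
          stop("node crossing during step: reduce the step-size factors (dt control)");
        rs[i] = mass[i] / hi;
      }
      force_balance(xs, rs, eta, gamma, s, rho_pref, v2);
      for (int i = 0; i < n; ++i) x[i] += 0.5 * dt * (v[i] + v2[i]);
      for (int i = 0; i < N; ++i) {
        double hi = x[i + 1] - x[i];
        if (!(hi > 0.0))
          stop("node crossing during step: reduce the step-size factors (dt control)");
        rho[i] = mass[i] / hi;
      }
      t += dt;
    }
    t = t_next;  // snap to the record time (integration hit it exactly)
    record();
    ++k;
    if (!explicit_times) {
      double eps = (W0 - (x[N] - x[0])) / W0;
      if (eps >= eps_stop) break;
    }
  }

  const int n_out = rec_t.size();
  NumericVector times(n_out);
  NumericMatrix pos(n, n_out), dens(N, n_out), vel(n, n_out);
  for (int j = 0; j < n_out; ++j) {
    times[j] = rec_t[j];
    for (int i = 0; i < n; ++i) { pos(i, j) = rec_x[j][i]; vel(i, j) = rec_v[j][i]; }
    for (int i = 0; i < N; ++i) dens(i, j) = rec_rho[j][i];
  }
  return List::create(_["times"] = times, _["positions"] = pos,
                      _["densities"] = dens, _["velocities"] = vel,
                      _["n_steps"] = steps, _["converged"] = converged);
}

// Weighted accumulation: out[idx[i]] += w[i] (1-based idx).  Used by the
// conservative (area-weighted) frame rotation.
// [[Rcpp::export]]
NumericVector bin_add(IntegerVector idx, NumericVector w, int n) {
  NumericVector out(n);
  const int m = idx.size();
  for (int i = 0; i < m; ++i) out[idx[i] - 1] += w[i];
  return out;
}
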