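#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Toy force fields evaluated natively so the integrator never calls back
// into R.  Kind codes: 0 harmonic, 1 double_well_1d, 2 triple_well_2d,
// 3 switch_chain.  Units: kcal/mol, Angstrom, amu, ps.

static const double KCAL = 418.4;          // 1 kcal/mol in amu A^2 ps^-2
static const double KB = 0.0019872041;     // kcal/mol/K

static double ff_energy_grad(int kind, const NumericVector& p,
                             const std::vector<double>& x,
                             std::vector<double>& g) {
  const int n = (int)x.size();
  std::fill(g.begin(), g.end(), 0.0);
  double U = 0.0;
  if (kind == 0) { // harmonic: p = [k, c1..cn]
    const double k = p[0];
    for (int i = 0; i < n; ++i) {
      const double d = x[i] - p[1 + i];
      U += 0.5 * k * d * d;
      g[i] += k * d;
    }
  } else if (kind == 1) { // double well: U = h*((x^2-b^2)/b^2)^2
    const double h = p[0], b = p[1], b2 = b * b;
    const double q = (x[0] * x[0] - b2) / b2;
    U = h * q * q;
    g[0] = 4.0 * h * q * x[0] / b2;
  } else if (kind == 2) { // triple well 2D: p = [kc, (cx,cy,depth,w) x 3]
    const double kc = p[0];
    U = 0.5 * kc * (x[0] * x[0] + x[1] * x[1]);
    g[0] = kc * x[0];
    g[1] = kc * x[1];
    for (int w = 0; w < 3; ++w) {
      const double cx = p[1 + 4 * w], cy = p[2 + 4 * w];
      const double d = p[3 + 4 * w], s = p[4 + 4 * w];
      const double dx = x[0] - cx, dy = x[1] - cy;
      const double e = std::exp(-(dx * dx + dy * dy) / (2.0 * s * s));
      U -= d * e;
      g[0] += d * e * dx / (s * s);
      g[1] += d * e * dy / (s * s);
    }
  } else if (kind == 3) {
    // switch chain: p = [nb, bond_k, r0, angle_k, theta0, i, j (1-based),
    //                    r1, r2, d1, d2, bias, barrier, w, wb, kw, rlo, rhi]
    const int nb = (int)p[0];
    const double bond_k = p[1], r0 = p[2], angle_k = p[3], theta0 = p[4];
    const int ia = (int)p[5] - 1, ja = (int)p[6] - 1;
    const double r1 = p[7], r2 = p[8], d1 = p[9], d2 = p[10];
    const double bias = p[11], barrier = p[12], w = p[13], wb = p[14];
    const double kw = p[15], rlo = p[16], rhi = p[17];
    // bonds
    for (int b = 0; b < nb - 1; ++b) {
      double dx[3], r = 0.0;
      for (int d = 0; d < 3; ++d) {
        dx[d] = x[3 * (b + 1) + d] - x[3 * b + d];
        r += dx[d] * dx[d];
      }
      r = std::sqrt(r);
      const double dr = r - r0;
      U += 0.5 * bond_k * dr * dr;
      const double f = bond_k * dr / r;
      for (int d = 0; d < 3; ++d) {
        g[3 * (b + 1) + d] += f * dx[d];
        g[3 * b + d] -= f * dx[d];
      }
    }
    // angles (harmonic in theta, guarded near sin(theta) = 0)
    for (int a = 1; a < nb - 1; ++a) {
      double u[3], v[3], lu = 0.0, lv = 0.0, c = 0.0;
      for (int d = 0; d < 3; ++d) {
        u[d] = x[3 * (a - 1) + d] - x[3 * a + d];
        v[d] = x[3 * (a + 1) + d] - x[3 * a + d];
        lu += u[d] * u[d];
        lv += v[d] * v[d];
        c += u[d] * v[d];
      }
      lu = std::sqrt(lu);
      lv = std::sqrt(lv);
      c /= (lu * lv);
      if (c > 1.0) c = 1.0;
      if (c < -1.0) c = -1.0;
      const double th = std::acos(c);
      const double dth = th - theta0;
      U += 0.5 * angle_k * dth * dth;
      double s = std::sqrt(1.0 - c * c);
      if (s < 1e-8) s = 1e-8;
      const double pref = -angle_k * dth / s; // dE/dc
      for (int d = 0; d < 3; ++d) {
        const double dci = (v[d] / lv - c * u[d] / lu) / lu;
        const double dck = (u[d] / lu - c * v[d] / lv) / lv;
        g[3 * (a - 1) + d] += pref * dci;
        g[3 * (a + 1) + d] += pref * dck;
        g[3 * a + d] -= pref * (dci + dck);
      }
    }
    // two-state pair potential on the switch pair: Gaussian wells at r1
    // (compact, depth d1 + bias) and r2 (incompact, depth d2), a Gaussian
    // barrier bump at the midpoint, and soft confining walls.
    {
      double dx[3], r = 0.0;
      for (int d = 0; d < 3; ++d) {
        dx[d] = x[3 * ja + d] - x[3 * ia + d];
        r += dx[d] * dx[d];
      }
      r = std::sqrt(r);
      const double rm = 0.5 * (r1 + r2);
      const double e1 = std::exp(-(r - r1) * (r - r1) / (2.0 * w * w));
      const double e2 = std::exp(-(r - r2) * (r - r2) / (2.0 * w * w));
      const double eb = std::exp(-(r - rm) * (r - rm) / (2.0 * wb * wb));
      U += (bias - d1) * e1 - d2 * e2 + barrier * eb;
      double dUdr = -(bias - d1) * e1 * (r - r1) / (w * w)
                    + d2 * e2 * (r - r2) / (w * w)
                    - barrier * eb * (r - rm) / (wb * wb);
      if (r < rlo) {
        U += 0.5 * kw * (r - rlo) * (r - rlo);
        dUdr += kw * (r - rlo);
      } else if (r > rhi) {
        U += 0.5 * kw * (r - rhi) * (r - rhi);
        dUdr += kw * (r - rhi);
      }
      const double f = dUdr / r;
      for (int d = 0; d < 3; ++d) {
        g[3 * ja + d] += f * dx[d];
        g[3 * ia + d] -= f * dx[d];
      }
    }
  } else {
    stop("unknown force-field kind code");
  }
  return U;
}

// [[Rcpp::export]]
List ff_eval_cpp(int kind, NumericVector params, NumericVector x) {
  std::vector<double> xv(x.begin(), x.end());
  std::vector<double> g(xv.size(), 0.0);
  double U = ff_energy_grad(kind, params, xv, g);
  return List::create(_["energy"] = U,
                      _["gradient"] = NumericVector(g.begin(), g.end()));
}

// One Langevin segment with BAOAB splitting.  When boost_on, forces on the
// region V < E are scaled by (1 - k (E - V)) and the boost energy
// dV = k (E - V)^2 / 2 is logged for stored steps.  Running potential-energy
// statistics (min/max and Welford mean/variance over every integration step)
// continue from the passed state so staged protocols can accumulate.
// [[Rcpp::export]]
List langevin_segment_cpp(int kind, NumericVector params,
                          NumericVector x0, NumericVector v0,
                          NumericVector masses, double dt, double temperature,
                          double friction, int n_steps, int stride,
                          bool boost_on, double E, double k,
                          double vmax0, double vmin0, double mean0,
                          double m2_0, double nstat0) {
  const int n = x0.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> g(n, 0.0), f(n, 0.0);
  const double c1 = (friction > 0.0) ? std::exp(-friction * dt) : 1.0;
  const double c2 = std::sqrt(1.0 - c1 * c1);
  std::vector<double> sig(n), inv_m(n);
  for (int i = 0; i < n; ++i) {
    inv_m[i] = KCAL / masses[i];
    sig[i] = std::sqrt(KB * temperature * inv_m[i]);
  }
  const int n_store = (stride > 0) ? n_steps / stride : 0;
  NumericMatrix frames(n_store, n);
  NumericVector Vs(n_store), dVs(n_store);
  IntegerVector steps(n_store);

  double vmax = vmax0, vmin = vmin0, mean = mean0, m2 = m2_0, nstat = nstat0;
  double V = ff_energy_grad(kind, params, x, g);
  double scale = 1.0;
  if (boost_on && V < E) scale = 1.0 - k * (E - V);
  for (int i = 0; i < n; ++i) f[i] = -g[i] * scale;

  int stored = 0;
  for (int s = 1; s <= n_steps; ++s) {
    for (int i = 0; i < n; ++i) v[i] += 0.5 * dt * f[i] * inv_m[i];
    for (int i = 0; i < n; ++i) x[i] += 0.5 * dt * v[i];
    for (int i = 0; i < n; ++i) v[i] = c1 * v[i] + c2 * sig[i] * R::norm_rand();
    for (int i = 0; i < n; ++i) x[i] += 0.5 * dt * v[i];
    V = ff_energy_grad(kind, params, x, g);
    if (!std::isfinite(V)) stop("non-finite potential energy at step %d", s);
    scale = 1.0;
    double dV = 0.0;
    if (boost_on && V < E) {
      scale = 1.0 - k * (E - V);
      dV = 0.5 * k * (E - V) * (E - V);
    }
    for (int i = 0; i < n; ++i) {
      f[i] = -g[i] * scale;
      v[i] += 0.5 * dt * f[i] * inv_m[i];
    }
    // running stats on the unbiased potential
    if (V > vmax) vmax = V;
    if (V < vmin) vmin = V;
    nstat += 1.0;
    const double d = V - mean;
    mean += d / nstat;
    m2 += d * (V - mean);
    if (stride > 0 && s % stride == 0 && stored < n_store) {
      for (int i = 0; i < n; ++i) frames(stored, i) = x[i];
      Vs[stored] = V;
      dVs[stored] = dV;
      steps[stored] = s;
      ++stored;
    }
  }
  return List::create(
    _["x"] = NumericVector(x.begin(), x.end()),
    _["v"] = NumericVector(v.begin(), v.end()),
    _["frames"] = frames, _["V"] = Vs, _["dV"] = dVs, _["steps"] = steps,
    _["vmax"] = vmax, _["vmin"] = vmin, _["mean"] = mean, _["m2"] = m2,
    _["nstat"] = nstat);
}
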