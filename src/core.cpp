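// Compiled cores: BAOAB Langevin integration on 1D analytic landscapes,
// well-tempered multiple-walker metadynamics with a gridded bias, and
// unbiased shooting/committor trajectories.  All randomness goes through
// R's RNG so set.seed() on the R side makes every run bit-reproducible.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double KB_KCAL = 0.0019872; // kcal/mol/K

namespace {

struct Pot {
  std::vector<double> c, h, w; // Gaussian centers, signed heights, widths
  double lo, hi, kwall;        // soft-wall domain
  double hk, hc;               // optional harmonic term (hk <= 0: absent)
  bool has_bias;
  const double *bias;          // external bias energies on a uniform grid
  int nb;
  double glo, gdx;

  double bias_energy(double x) const {
    if (!has_bias) return 0.0;
    double u = (x - glo) / gdx;
    if (u <= 0.0) return bias[0];
    if (u >= nb - 1) return bias[nb - 1];
    int i = (int)u;
    double f = u - i;
    return bias[i] * (1.0 - f) + bias[i + 1] * f;
  }
  double bias_force(double x) const {
    if (!has_bias) return 0.0;
    double u = (x - glo) / gdx;
    if (u <= 0.0 || u >= nb - 1) return 0.0;
    int i = (int)u;
    return -(bias[i + 1] - bias[i]) / gdx;
  }
  double energy(double x) const {
    double e = 0.0;
    for (size_t j = 0; j < c.size(); ++j) {
      double z = (x - c[j]) / w[j];
      e += h[j] * std::exp(-0.5 * z * z);
    }
    if (hk > 0.0) {
      double d = x - hc;
      e += 0.5 * hk * d * d;
    }
    if (x < lo) {
      double d = x - lo;
      e += 0.5 * kwall * d * d;
    }
    if (x > hi) {
      double d = x - hi;
      e += 0.5 * kwall * d * d;
    }
    return e + bias_energy(x);
  }
  double force(double x) const {
    double f = 0.0;
    for (size_t j = 0; j < c.size(); ++j) {
      double d = x - c[j];
      double z = d / w[j];
      f += h[j] * std::exp(-0.5 * z * z) * d / (w[j] * w[j]);
    }
    if (hk > 0.0) f -= hk * (x - hc);
    if (x < lo) f -= kwall * (x - lo);
    if (x > hi) f -= kwall * (x - hi);
    return f + bias_force(x);
  }
};

Pot make_pot(const NumericVector &centers, const NumericVector &heights,
             const NumericVector &widths, double lo, double hi, double kwall,
             double hk, double hc) {
  Pot p;
  p.c = as<std::vector<double> >(centers);
  p.h = as<std::vector<double> >(heights);
  p.w = as<std::vector<double> >(widths);
  p.lo = lo;
  p.hi = hi;
  p.kwall = kwall;
  p.hk = hk;
  p.hc = hc;
  p.has_bias = false;
  p.bias = 0;
  p.nb = 0;
  p.glo = 0.0;
  p.gdx = 1.0;
  return p;
}

// one BAOAB step; returns updated force (at the new position)
inline void baoab_step(const Pot &p, double &x, double &v, double &fx,
                       double dt, double c1, double c2, double sig,
                       double invm) {
  v += 0.5 * dt * fx * invm;
  x += 0.5 * dt * v;
  v = c1 * v + c2 * sig * norm_rand();
  x += 0.5 * dt * v;
  fx = p.force(x);
  v += 0.5 * dt * fx * invm;
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_potential(NumericVector x, NumericVector centers,
                            NumericVector heights, NumericVector widths,
                            double lo, double hi, double kwall, double hk,
                            double hc) {
  Pot p = make_pot(centers, heights, widths, lo, hi, kwall, hk, hc);
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = p.energy(x[i]);
  return out;
}

// [[Rcpp::export]]
List cpp_langevin(NumericVector centers, NumericVector heights,
                  NumericVector widths, double lo, double hi, double kwall,
                  double hk, double hc, double x0, double v0, bool draw_v0,
                  int nsteps, double dt, int stride, double friction,
                  double temp, double mass, Nullable<NumericVector> biasgrid,
                  double glo, double gdx) {
  Pot p = make_pot(centers, heights, widths, lo, hi, kwall, hk, hc);
  NumericVector bg;
  if (biasgrid.isNotNull()) {
    bg = biasgrid.get();
    p.has_bias = true;
    p.bias = REAL(bg);
    p.nb = bg.size();
    p.glo = glo;
    p.gdx = gdx;
  }
  RNGScope scope;
  const double kT = KB_KCAL * temp;
  const double invm = 1.0 / mass;
  const double c1 = std::exp(-friction * dt);
  const double c2 = std::sqrt(1.0 - c1 * c1);
  const double sig = std::sqrt(kT * invm);
  double x = x0;
  double v = draw_v0 ? sig * norm_rand() : v0;
  if (temp <= 0.0) v = draw_v0 ? 0.0 : v0;
  double fx = p.force(x);
  const double span = hi - lo;
  int nrec = nsteps / stride;
  NumericVector xs(nrec), vs(nrec), ts(nrec);
  bool diverged = false;
  double tdiv = NA_REAL;
  int k = 0;
  for (int i = 1; i <= nsteps; ++i) {
    if (temp > 0.0) {
      baoab_step(p, x, v, fx, dt, c1, c2, sig, invm);
    } else { // deterministic limit: velocity Verlet with friction
      v += 0.5 * dt * fx * invm;
      x += 0.5 * dt * v;
      v = c1 * v;
      x += 0.5 * dt * v;
      fx = p.force(x);
      v += 0.5 * dt * fx * invm;
    }
    if (x < lo - 10.0 * span || x > hi + 10.0 * span || !std::isfinite(x)) {
      diverged = true;
      tdiv = i * dt;
      break;
    }
    if (i % stride == 0 && k < nrec) {
      xs[k] = x;
      vs[k] = v;
      ts[k] = i * dt;
      ++k;
    }
  }
  if (diverged && k < nrec) {
    xs = head(xs, k);
    vs = head(vs, k);
    ts = head(ts, k);
  }
  return List::create(_["time_ps"] = ts, _["s"] = xs, _["v"] = vs,
                      _["final_x"] = x, _["final_v"] = v,
                      _["diverged"] = diverged, _["t_diverged"] = tdiv);
}

// Well-tempered metadynamics, nwalkers sharing a single gridded bias.
// biasf <= 0 encodes the standard (infinite bias factor) variant.
// [[Rcpp::export]]
List cpp_metad(NumericVector centers, NumericVector heights,
               NumericVector widths, double lo, double hi, double kwall,
               double hk, double hc, NumericVector x0, int nsteps, double dt,
               int stride, double friction, double temp, double mass,
               double w0, double sigma, double biasf, int pace, double glo,
               double ghi, double gdx) {
  Pot p = make_pot(centers, heights, widths, lo, hi, kwall, hk, hc);
  RNGScope scope;
  const double kT = KB_KCAL * temp;
  const double invm = 1.0 / mass;
  const double c1 = std::exp(-friction * dt);
  const double c2 = std::sqrt(1.0 - c1 * c1);
  const double sig = std::sqrt(kT * invm);
  const int nw = x0.size();
  const int nb = (int)std::floor((ghi - glo) / gdx) + 1;
  NumericVector bias(nb); // shared bias grid, kcal/mol
  p.has_bias = true;
  p.bias = REAL(bias);
  p.nb = nb;
  p.glo = glo;
  p.gdx = gdx;

  std::vector<double> x(nw), v(nw), fx(nw);
  for (int wI = 0; wI < nw; ++wI) {
    x[wI] = x0[wI];
    v[wI] = sig * norm_rand();
    fx[wI] = p.force(x[wI]);
  }
  const int nblocks = nsteps / pace;
  const int nhills = nblocks * nw;
  NumericVector h_time(nhills), h_center(nhills), h_height(nhills);
  IntegerVector h_walker(nhills);
  int nrec = nsteps / stride;
  NumericMatrix traj(nrec, nw);
  NumericVector rec_t(nrec);
  const double span = hi - lo;
  const double dT = (biasf > 0.0) ? (biasf - 1.0) * temp : 0.0;
  int hk_i = 0;
  bool diverged = false;
  for (int b = 0; b < nblocks; ++b) {
    for (int wI = 0; wI < nw; ++wI) {
      double xx = x[wI], vv = v[wI], ff = fx[wI];
      for (int i = 0; i < pace; ++i) {
        baoab_step(p, xx, vv, ff, dt, c1, c2, sig, invm);
      }
      if (xx < lo - 10.0 * span || xx > hi + 10.0 * span ||
          !std::isfinite(xx)) {
        diverged = true;
        break;
      }
      x[wI] = xx;
      v[wI] = vv;
      fx[wI] = ff;
      // deposit a hill at the walker's position
      double hh = w0;
      if (biasf > 0.0) hh = w0 * std::exp(-p.bias_energy(xx) / (KB_KCAL * dT));
      int i0 = (int)std::floor((xx - 6.0 * sigma - glo) / gdx);
      int i1 = (int)std::ceil((xx + 6.0 * sigma - glo) / gdx);
      if (i0 < 0) i0 = 0;
      if (i1 > nb - 1) i1 = nb - 1;
      for (int i = i0; i <= i1; ++i) {
        double z = (glo + i * gdx - xx) / sigma;
        bias[i] += hh * std::exp(-0.5 * z * z);
      }
      h_time[hk_i] = (b + 1) * pace * dt;
      h_center[hk_i] = xx;
      h_height[hk_i] = hh;
      h_walker[hk_i] = wI + 1;
      ++hk_i;
      // record strided positions (per block bookkeeping below)
    }
    if (diverged) break;
    // record: block end corresponds to step (b+1)*pace
    int step_now = (b + 1) * pace;
    for (int sstep = b * pace + 1; sstep <= step_now; ++sstep) {
      if (sstep % stride == 0) {
        int idx = sstep / stride - 1;
        if (idx >= 0 && idx < nrec) {
          rec_t[idx] = sstep * dt;
          for (int wI = 0; wI < nw; ++wI) traj(idx, wI) = x[wI];
        }
      }
    }
  }
  if (hk_i < nhills) {
    h_time = head(h_time, hk_i);
    h_center = head(h_center, hk_i);
    h_height = head(h_height, hk_i);
    h_walker = head(h_walker, hk_i);
  }
  return List::create(_["hill_time"] = h_time, _["hill_center"] = h_center,
                      _["hill_height"] = h_height, _["hill_walker"] = h_walker,
                      _["rec_time"] = rec_t, _["traj"] = traj,
                      _["bias_grid"] = bias, _["grid_lo"] = glo,
                      _["grid_dx"] = gdx, _["diverged"] = diverged);
}

// Unbiased shooting: integrate each (x0, v0) until commitment to the bound
// side (x <= a_abs), the unbound side (x >= b_abs) or timeout.
// outcome: 0 = bound, 1 = unbound, 2 = timeout.
// [[Rcpp::export]]
List cpp_shoot(NumericVector centers, NumericVector heights,
               NumericVector widths, double lo, double hi, double kwall,
               double hk, double hc, NumericVector x0, NumericVector v0,
               double a_abs, double b_abs, double dt, double friction,
               double temp, double mass, double max_steps) {
  Pot p = make_pot(centers, heights, widths, lo, hi, kwall, hk, hc);
  RNGScope scope;
  const double kT = KB_KCAL * temp;
  const double invm = 1.0 / mass;
  const double c1 = std::exp(-friction * dt);
  const double c2 = std::sqrt(1.0 - c1 * c1);
  const double sig = std::sqrt(kT * invm);
  const int n = x0.size();
  IntegerVector outcome(n);
  NumericVector fpt(n);
  for (int t = 0; t < n; ++t) {
    double x = x0[t], v = v0[t];
    double fx = p.force(x);
    int out = 2;
    double steps = 0.0;
    while (steps < max_steps) {
      baoab_step(p, x, v, fx, dt, c1, c2, sig, invm);
      steps += 1.0;
      if (x <= a_abs) {
        out = 0;
        break;
      }
      if (x >= b_abs) {
        out = 1;
        break;
      }
    }
    outcome[t] = out;
    fpt[t] = steps * dt;
    if (t % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["outcome"] = outcome, _["fpt_ps"] = fpt);
}
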