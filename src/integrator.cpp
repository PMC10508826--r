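#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Analytic toy potentials, energies in kBT (kBT = 1 internally).
// code 1: quartic double well + linear tilt (1-D): U = h*(x^2-1)^2 + tilt*x
//         par = [h, tilt]
// code 2: 2-D Gaussian-mixture free-energy surface:
//         U = -log( sum_k a_k exp(-(x-cx_k)^2/(2 sx_k^2) - (y-cy_k)^2/(2 sy_k^2)) )
//         par = [K, a_1..a_K, cx_1..cx_K, cy_1..cy_K, sx_1..sx_K, sy_1..sy_K]
// code 3: scaled Mueller-Brown surface (2-D), par = [scale]
// code 4: harmonic well (1-D): U = 0.5*k*(x-x0)^2, par = [k, x0]
static inline double pot_eval(int code, const double* par, const double* x,
                              double* g, int dim) {
  if (code == 1) {
    double h = par[0], tilt = par[1];
    double q = x[0] * x[0] - 1.0;
    g[0] = 4.0 * h * q * x[0] + tilt;
    return h * q * q + tilt * x[0];
  } else if (code == 2) {
    int K = (int) par[0];
    const double* a  = par + 1;
    const double* cx = par + 1 + K;
    const double* cy = par + 1 + 2 * K;
    const double* sx = par + 1 + 3 * K;
    const double* sy = par + 1 + 4 * K;
    double p = 0.0, gx = 0.0, gy = 0.0;
    for (int k = 0; k < K; ++k) {
      double dx = x[0] - cx[k], dy = x[1] - cy[k];
      double e = a[k] * std::exp(-0.5 * dx * dx / (sx[k] * sx[k])
                                 -0.5 * dy * dy / (sy[k] * sy[k]));
      p  += e;
      gx += e * dx / (sx[k] * sx[k]);
      gy += e * dy / (sy[k] * sy[k]);
    }
    p += 1e-300;  // guard far tails
    g[0] = gx / p;
    g[1] = gy / p;
    return -std::log(p);
  } else if (code == 3) {
    static const double A[4]  = {-200, -100, -170, 15};
    static const double aa[4] = {-1, -1, -6.5, 0.7};
    static const double bb[4] = {0, 0, 11, 0.6};
    static const double cc[4] = {-10, -10, -6.5, 0.7};
    static const double X0[4] = {1, 0, -0.5, -1};
    static const double Y0[4] = {0, 0.5, 1.5, 1};
    double s = par[0], u = 0.0, gx = 0.0, gy = 0.0;
    for (int i = 0; i < 4; ++i) {
      double dx = x[0] - X0[i], dy = x[1] - Y0[i];
      double e = A[i] * std::exp(aa[i] * dx * dx + bb[i] * dx * dy + cc[i] * dy * dy);
      u  += e;
      gx += e * (2 * aa[i] * dx + bb[i] * dy);
      gy += e * (bb[i] * dx + 2 * cc[i] * dy);
    }
    g[0] = s * gx;
    g[1] = s * gy;
    return s * u;
  } else if (code == 4) {
    double k = par[0], x0 = par[1];
    g[0] = k * (x[0] - x0);
    return 0.5 * k * (x[0] - x0) * (x[0] - x0);
  }
  stop("unknown potential code");
  return 0.0;
}

// Discrete-state classifiers on the raw coordinates.
// code 0: none (always -1)
// code 1: two-state 1-D sign rule: x < 0 -> 0 ("A"), x >= 0 -> 1 ("B")
// code 2: Dunbrack rule on (d1, d2):
//         0 IN, 1 OUT, 2 INTER, 3 UNASSIGNED, 4 GAP
static inline int classify_state(int code, const double* x) {
  if (code == 0) return -1;
  if (code == 1) return x[0] < 0.0 ? 0 : 1;
  if (code == 2) {
    double d1 = x[0], d2 = x[1];
    if (d1 < 11.0 && d2 > 14.0) return 0;
    if (d1 > 11.0 && d2 < 14.0) return 1;
    if (d1 < 11.0 && d2 < 11.0) return 2;
    if (d1 > 11.0 && d2 > 14.0) return 3;
    return 4;
  }
  stop("unknown classifier code");
  return -1;
}

// Grid cache of the bias and its gradient over the IB coordinates.
// Kernel tails are truncated at 8 sigma when accumulated on the grid; the
// kernel list itself is kept exact for serialization and reweighting.
struct BiasGrid {
  int ds;
  double lo[2], hi[2], h[2];
  int nb[2];
  std::vector<double> V, G0, G1;

  void init(int ds_, const double* lo_, const double* hi_, const int* nb_) {
    ds = ds_;
    size_t tot = 1;
    for (int d = 0; d < ds; ++d) {
      lo[d] = lo_[d];
      hi[d] = hi_[d];
      nb[d] = nb_[d];
      if (nb[d] < 2) stop("bias grid needs >= 2 nodes per dimension");
      if (!(hi[d] > lo[d]) || !std::isfinite(lo[d]) || !std::isfinite(hi[d]))
        stop("bias grid bounds must be finite with hi > lo");
      h[d] = (hi[d] - lo[d]) / (nb[d] - 1);
      tot *= (size_t) nb[d];
    }
    V.assign(tot, 0.0);
    G0.assign(tot, 0.0);
    if (ds == 2) G1.assign(tot, 0.0);
  }

  void add_kernel(const double* c, const double* sg, double height) {
    const double cut = 8.0;
    if (ds == 1) {
      int i0 = std::max(0, (int) std::floor((c[0] - cut * sg[0] - lo[0]) / h[0]));
      int i1 = std::min(nb[0] - 1, (int) std::ceil((c[0] + cut * sg[0] - lo[0]) / h[0]));
      for (int i = i0; i <= i1; ++i) {
        double d0 = lo[0] + i * h[0] - c[0];
        double e = height * std::exp(-0.5 * d0 * d0 / (sg[0] * sg[0]));
        V[i]  += e;
        G0[i] += -e * d0 / (sg[0] * sg[0]);
      }
    } else {
      int i0 = std::max(0, (int) std::floor((c[0] - cut * sg[0] - lo[0]) / h[0]));
      int i1 = std::min(nb[0] - 1, (int) std::ceil((c[0] + cut * sg[0] - lo[0]) / h[0]));
      int j0 = std::max(0, (int) std::floor((c[1] - cut * sg[1] - lo[1]) / h[1]));
      int j1 = std::min(nb[1] - 1, (int) std::ceil((c[1] + cut * sg[1] - lo[1]) / h[1]));
      for (int i = i0; i <= i1; ++i) {
        double d0 = lo[0] + i * h[0] - c[0];
        double e0 = std::exp(-0.5 * d0 * d0 / (sg[0] * sg[0]));
        for (int j = j0; j <= j1; ++j) {
          double d1 = lo[1] + j * h[1] - c[1];
          double e = height * e0 * std::exp(-0.5 * d1 * d1 / (sg[1] * sg[1]));
          size_t idx = (size_t) i * nb[1] + j;
          V[idx]  += e;
          G0[idx] += -e * d0 / (sg[0] * sg[0]);
          G1[idx] += -e * d1 / (sg[1] * sg[1]);
        }
      }
    }
  }

  // Bilinear interpolation of V and its gradient; coordinates outside the
  // grid are clamped to the boundary (zero slope beyond it).
  void eval(const double* s, double* grad, double* Vout) const {
    double sc[2];
    int i[2];
    double f[2];
    for (int d = 0; d < ds; ++d) {
      sc[d] = s[d];
      if (sc[d] <= lo[d]) sc[d] = lo[d];
      if (sc[d] >= hi[d]) sc[d] = hi[d];
      double u = (sc[d] - lo[d]) / h[d];
      i[d] = std::min((int) std::floor(u), nb[d] - 2);
      f[d] = u - i[d];
    }
    if (ds == 1) {
      *Vout   = V[i[0]]  * (1 - f[0]) + V[i[0] + 1]  * f[0];
      grad[0] = G0[i[0]] * (1 - f[0]) + G0[i[0] + 1] * f[0];
    } else {
      size_t i00 = (size_t) i[0] * nb[1] + i[1];
      size_t i01 = i00 + 1;
      size_t i10 = i00 + nb[1];
      size_t i11 = i10 + 1;
      double w00 = (1 - f[0]) * (1 - f[1]), w01 = (1 - f[0]) * f[1];
      double w10 = f[0] * (1 - f[1]), w11 = f[0] * f[1];
      *Vout   = w00 * V[i00]  + w01 * V[i01]  + w10 * V[i10]  + w11 * V[i11];
      grad[0] = w00 * G0[i00] + w01 * G0[i01] + w10 * G0[i10] + w11 * G0[i11];
      grad[1] = w00 * G1[i00] + w01 * G1[i01] + w10 * G1[i10] + w11 * G1[i11];
    }
  }
};

// Exact kernel-sum bias (no truncation); used for well-tempered deposit
// heights and exported for fast evaluation of a kernel list at many points.
static inline double kernel_sum(const std::vector<double>* kc,
                                const std::vector<double>* ks,
                                const std::vector<double>& kh,
                                int ds, const double* s) {
  double v = 0.0;
  size_t n = kh.size();
  for (size_t k = 0; k < n; ++k) {
    double q = 0.0;
    for (int d = 0; d < ds; ++d) {
      double dd = s[d] - kc[d][k];
      q += 0.5 * dd * dd / (ks[d][k] * ks[d][k]);
    }
    v += kh[k] * std::exp(-q);
  }
  return v;
}

// Vectorized potential energies (and optionally gradients) for a matrix of
// configurations; used by the quadrature routines in R.
// [[Rcpp::export]]
NumericVector cpp_pot_energy(int code, NumericVector par, NumericMatrix X) {
  int n = X.nrow(), dim = X.ncol();
  NumericVector out(n);
  std::vector<double> x(dim), g(dim);
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < dim; ++d) x[d] = X(i, d);
    out[i] = pot_eval(code, par.begin(), x.data(), g.data(), dim);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_eval_bias(NumericMatrix centers, NumericMatrix sigmas,
                            NumericVector heights, NumericMatrix S) {
  int ds = centers.ncol();
  int n = centers.nrow(), m = S.nrow();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double v = 0.0;
    for (int k = 0; k < n; ++k) {
      double q = 0.0;
      for (int d = 0; d < ds; ++d) {
        double dd = S(i, d) - centers(k, d);
        q += 0.5 * dd * dd / (sigmas(k, d) * sigmas(k, d));
      }
      v += heights[k] * std::exp(-q);
    }
    out[i] = v;
  }
  return out;
}

// Plain BAOAB Langevin integrator (unit mass), recording positions,
// velocities and potential energies every `stride` steps.
// [[Rcpp::export]]
List cpp_baoab(int pot_code, NumericVector pot_par, NumericVector x0,
               double dt, double friction, double kBT,
               int n_steps, int stride, double guard) {
  int dim = x0.size();
  std::vector<double> x(x0.begin(), x0.end()), v(dim, 0.0), g(dim, 0.0);
  double U = pot_eval(pot_code, pot_par.begin(), x.data(), g.data(), dim);
  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt(kBT * (1.0 - c1 * c1));
  int nrec = n_steps / stride + 1;
  NumericMatrix X(nrec, dim), Vel(nrec, dim);
  NumericVector E(nrec), steps(nrec);
  int r = 0;
  for (int d = 0; d < dim; ++d) { X(0, d) = x[d]; Vel(0, d) = v[d]; }
  E[0] = U; steps[0] = 0; r = 1;
  for (int t = 0; t < n_steps; ++t) {
    for (int d = 0; d < dim; ++d) v[d] -= 0.5 * dt * g[d];
    for (int d = 0; d < dim; ++d) x[d] += 0.5 * dt * v[d];
    for (int d = 0; d < dim; ++d) v[d] = c1 * v[d] + c2 * norm_rand();
    for (int d = 0; d < dim; ++d) x[d] += 0.5 * dt * v[d];
    U = pot_eval(pot_code, pot_par.begin(), x.data(), g.data(), dim);
    for (int d = 0; d < dim; ++d) v[d] -= 0.5 * dt * g[d];
    for (int d = 0; d < dim; ++d)
      if (!std::isfinite(x[d]) || std::fabs(x[d]) > guard)
        stop("trajectory diverged at step %d", t + 1);
    if ((t + 1) % stride == 0) {
      for (int d = 0; d < dim; ++d) { X(r, d) = x[d]; Vel(r, d) = v[d]; }
      E[r] = U; steps[r] = t + 1; ++r;
    }
  }
  return List::create(_["steps"] = steps, _["x"] = X, _["v"] = Vel,
                      _["energy"] = E);
}

// Multi-walker (well-tempered) metadynamics / static-bias dynamics on the
// IB coordinates s = W x + b of a toy potential.  All walkers share one
// kernel list; deposits every `pace` steps unless `frozen`.  Each walker
// halts once its stop rule holds: classifier state equal to its target
// continuously for `window` steps (target -2 accepts either main state 0/1,
// target -1 disables the rule).  kBT = 1.
// [[Rcpp::export]]
List cpp_run_walkers(int pot_code, NumericVector pot_par,
                     NumericMatrix x0, NumericMatrix encW, NumericVector encb,
                     bool frozen, double w0, NumericVector sigma_g,
                     int pace, double gamma_f,
                     NumericMatrix init_centers, NumericMatrix init_sigmas,
                     NumericVector init_heights,
                     NumericVector grid_lo, NumericVector grid_hi,
                     IntegerVector grid_nb,
                     double dt, double friction, int max_steps, int stride,
                     int classifier, IntegerVector target_state, int window,
                     double guard, bool halt_on_stop) {
  int nw = x0.nrow(), dim = x0.ncol(), ds = encW.nrow();
  if (encW.ncol() != dim) stop("encoder width mismatch");
  if (!frozen && gamma_f <= 1.0) stop("bias factor must exceed 1");

  BiasGrid grid;
  grid.init(ds, grid_lo.begin(), grid_hi.begin(), grid_nb.begin());

  std::vector<double> kc[2], ksg[2];
  std::vector<double> kh, ktime, kwalker;
  for (int k = 0; k < init_heights.size(); ++k) {
    double c[2], sg[2];
    for (int d = 0; d < ds; ++d) {
      c[d] = init_centers(k, d);
      sg[d] = init_sigmas(k, d);
      kc[d].push_back(c[d]);
      ksg[d].push_back(sg[d]);
    }
    kh.push_back(init_heights[k]);
    ktime.push_back(-1.0);
    kwalker.push_back(0.0);
    grid.add_kernel(c, sg, init_heights[k]);
  }

  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt(1.0 - c1 * c1);

  std::vector<std::vector<double> > x(nw), v(nw), g(nw), f(nw);
  std::vector<bool> active(nw, true);
  std::vector<int> consec(nw, 0), last_main(nw, -9), stop_step(nw, -1);
  std::vector<std::vector<double> > rec(nw);  // step, x, s, V, state

  // force on walker w at its current x: -(dU/dx) - W^T dV/ds
  std::vector<double> s(2), dVds(2);
  double Vs;

  for (int w = 0; w < nw; ++w) {
    x[w].assign(dim, 0.0);
    for (int d = 0; d < dim; ++d) x[w][d] = x0(w, d);
    v[w].assign(dim, 0.0);
    g[w].assign(dim, 0.0);
    f[w].assign(dim, 0.0);
  }

  // helper lambdas
  auto project = [&](const std::vector<double>& xx, double* ss) {
    for (int d = 0; d < ds; ++d) {
      double acc = encb[d];
      for (int j = 0; j < dim; ++j) acc += encW(d, j) * xx[j];
      ss[d] = acc;
    }
  };
  auto total_force = [&](int w, double* Vout) {
    pot_eval(pot_code, pot_par.begin(), x[w].data(), g[w].data(), dim);
    project(x[w], s.data());
    grid.eval(s.data(), dVds.data(), &Vs);
    for (int j = 0; j < dim; ++j) {
      double fb = 0.0;
      for (int d = 0; d < ds; ++d) fb += encW(d, j) * dVds[d];
      f[w][j] = -g[w][j] - fb;
    }
    if (Vout) *Vout = Vs;
  };
  auto record = [&](int w, int step) {
    project(x[w], s.data());
    grid.eval(s.data(), dVds.data(), &Vs);
    int st = classify_state(classifier, x[w].data());
    rec[w].push_back((double) step);
    for (int d = 0; d < dim; ++d) rec[w].push_back(x[w][d]);
    for (int d = 0; d < ds; ++d) rec[w].push_back(s[d]);
    rec[w].push_back(Vs);
    rec[w].push_back((double) st);
  };

  for (int w = 0; w < nw; ++w) {
    total_force(w, NULL);
    record(w, 0);
  }

  for (int t = 0; t < max_steps; ++t) {
    bool any_active = false;
    for (int w = 0; w < nw; ++w) {
      if (!active[w]) continue;
      any_active = true;
      for (int d = 0; d < dim; ++d) v[w][d] += 0.5 * dt * f[w][d];
      for (int d = 0; d < dim; ++d) x[w][d] += 0.5 * dt * v[w][d];
      for (int d = 0; d < dim; ++d) v[w][d] = c1 * v[w][d] + c2 * norm_rand();
      for (int d = 0; d < dim; ++d) x[w][d] += 0.5 * dt * v[w][d];
      total_force(w, NULL);
      for (int d = 0; d < dim; ++d) v[w][d] += 0.5 * dt * f[w][d];
      for (int d = 0; d < dim; ++d)
        if (!std::isfinite(x[w][d]) || std::fabs(x[w][d]) > guard)
          stop("walker %d diverged at step %d", w + 1, t + 1);

      // stop rule
      int st = classify_state(classifier, x[w].data());
      int tgt = target_state[w];
      if (tgt == -2) {
        if (st == 0 || st == 1) {
          consec[w] = (st == last_main[w]) ? consec[w] + 1 : 1;
          last_main[w] = st;
        } else {
          consec[w] = 0;
          last_main[w] = -9;
        }
      } else if (tgt >= 0) {
        consec[w] = (st == tgt) ? consec[w] + 1 : 0;
      }
      if ((t + 1) % stride == 0) record(w, t + 1);
      if (tgt != -1 && consec[w] >= window && stop_step[w] < 0) {
        stop_step[w] = t + 1;
        if (halt_on_stop) {
          active[w] = false;
          if ((t + 1) % stride != 0) record(w, t + 1);
        }
      }
    }
    if (!any_active) break;

    // shared deposits (walkers deposit in index order at the same pace step)
    if (!frozen && (t + 1) % pace == 0) {
      for (int w = 0; w < nw; ++w) {
        if (!active[w]) continue;
        project(x[w], s.data());
        double Vexact = kernel_sum(kc, ksg, kh, ds, s.data());
        double hgt = w0 * std::exp(-Vexact / (gamma_f - 1.0));
        double c[2], sg2[2];
        for (int d = 0; d < ds; ++d) {
          c[d] = s[d];
          sg2[d] = sigma_g[d];
          kc[d].push_back(s[d]);
          ksg[d].push_back(sigma_g[d]);
        }
        kh.push_back(hgt);
        ktime.push_back((double) (t + 1));
        kwalker.push_back((double) (w + 1));
        grid.add_kernel(c, sg2, hgt);
        // bias changed: refresh forces of all active walkers
      }
      for (int w = 0; w < nw; ++w) if (active[w]) total_force(w, NULL);
    }
  }

  int ncol = 1 + dim + ds + 2;
  List traj(nw);
  for (int w = 0; w < nw; ++w) {
    int nr = rec[w].size() / ncol;
    NumericMatrix M(nr, ncol);
    for (int i = 0; i < nr; ++i)
      for (int j = 0; j < ncol; ++j)
        M(i, j) = rec[w][(size_t) i * ncol + j];
    traj[w] = M;
  }
  int nk = kh.size();
  NumericMatrix C(nk, ds), Sg(nk, ds);
  NumericVector H(nk), Tm(nk);
  IntegerVector Wk(nk);
  for (int k = 0; k < nk; ++k) {
    for (int d = 0; d < ds; ++d) { C(k, d) = kc[d][k]; Sg(k, d) = ksg[d][k]; }
    H[k] = kh[k];
    Tm[k] = ktime[k];
    Wk[k] = (int) kwalker[k];
  }
  IntegerVector SS(nw);
  for (int w = 0; w < nw; ++w) SS[w] = stop_step[w];
  return List::create(_["traj"] = traj, _["centers"] = C, _["sigmas"] = Sg,
                      _["heights"] = H, _["times"] = Tm, _["walker"] = Wk,
                      _["stop_step"] = SS);
}
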