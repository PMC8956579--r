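// Fixed-step RK4 ODE integration and semi-implicit Euler SDE simulation for
// the package's built-in vector fields.  Model ids and parameter-vector
// layouts must match R/model_core.R:
//   1 toggle    pars = (basal, strength, hill)                    dim 2
//   2 twonode   pars = (gain1, sat1, rep1, deg1, gain2, ...)      dim 2
//   3 tristable pars = (alpha1, beta1, beta2, k3, gamma1, sigma1, sigma2, k4,
//                       a1, b1, b2, k1, d2, 0, 0, 0, 0)           dim 3
//   4 quad      pars = tristable layout with (alpha0, gamma0, a0, d_star)
//                      in slots 14..17                            dim 3
// sched = (k0_star, t1, t2, psi); k* = k0_star on the closed window.
#include <Rcpp.h>
using namespace Rcpp;

static inline double kstar_at(const double *sched, double t) {
  return (t >= sched[1] && t <= sched[2]) ? sched[0] : 0.0;
}

static void drift(int model, const double *p, const double *sched, double t,
                  const double *s, double *out) {
  switch (model) {
  case 1: { // toggle
    out[0] = p[0] + p[1] / (1.0 + std::pow(s[1], p[2])) - s[0];
    out[1] = p[0] + p[1] / (1.0 + std::pow(s[0], p[2])) - s[1];
    break;
  }
  case 2: { // twonode Shea-Ackers
    out[0] = p[0] * s[0] / ((1.0 + p[1] * s[0]) * (1.0 + p[2] * s[1])) - p[3] * s[0];
    out[1] = p[4] * s[1] / ((1.0 + p[5] * s[1]) * (1.0 + p[6] * s[0])) - p[7] * s[1];
    break;
  }
  case 3:
  case 4: { // tristable / quad (state order x, y, z)
    const double x = s[0], y = s[1], z = s[2];
    const double ks = sched ? kstar_at(sched, t) : 0.0;
    const double psi = sched ? sched[3] : 0.0;
    const double a0x = p[13], a0y = p[14], a0z = p[15], dstar = p[16];
    out[0] = (a0x + p[0] * x) / (1.0 + p[1] * x) / (1.0 + p[2] * y) *
             (1.0 + dstar * z) / (1.0 + p[12] * z) - p[3] * x + psi * ks * z;
    out[1] = (a0y + p[4] * y) / (1.0 + p[5] * y) / (1.0 + p[6] * x) /
             (1.0 + p[12] * z) - p[7] * y;
    out[2] = (a0z + p[8] * z) / (1.0 + p[9] * z) / (1.0 + p[10] * (x + y)) -
             p[11] * z - ks * z;
    break;
  }
  default:
    stop("unknown model id");
  }
}

static inline int model_dim(int model) { return (model >= 3) ? 3 : 2; }

// RK4 path sampled at `times` (increasing, init given at times[0]); internal
// step <= dt, adjusted to land exactly on each sample time.
// [[Rcpp::export]]
NumericMatrix cpp_integrate(int model, NumericVector pars, NumericVector sched,
                            NumericVector init, NumericVector times, double dt) {
  if (dt <= 0) stop("dt must be > 0");
  const int dim = model_dim(model);
  if (init.size() != dim) stop("init has wrong dimension");
  const int m = times.size();
  const double *sc = (sched.size() == 4) ? &sched[0] : nullptr;
  NumericMatrix out(m, dim);
  std::vector<double> s(init.begin(), init.end());
  std::vector<double> k1(dim), k2(dim), k3(dim), k4(dim), tmp(dim);
  for (int j = 0; j < dim; ++j) out(0, j) = s[j];
  for (int i = 1; i < m; ++i) {
    double t0 = times[i - 1], t1 = times[i];
    if (t1 <= t0) stop("times must be strictly increasing");
    int nstep = (int)std::ceil((t1 - t0) / dt - 1e-12);
    double h = (t1 - t0) / nstep;
    double t = t0;
    for (int k = 0; k < nstep; ++k) {
      drift(model, &pars[0], sc, t, s.data(), k1.data());
      for (int j = 0; j < dim; ++j) tmp[j] = s[j] + 0.5 * h * k1[j];
      drift(model, &pars[0], sc, t + 0.5 * h, tmp.data(), k2.data());
      for (int j = 0; j < dim; ++j) tmp[j] = s[j] + 0.5 * h * k2[j];
      drift(model, &pars[0], sc, t + 0.5 * h, tmp.data(), k3.data());
      for (int j = 0; j < dim; ++j) tmp[j] = s[j] + h * k3[j];
      drift(model, &pars[0], sc, t + h, tmp.data(), k4.data());
      for (int j = 0; j < dim; ++j)
        s[j] += h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      t += h;
    }
    for (int j = 0; j < dim; ++j) out(i, j) = s[j];
  }
  return out;
}

// One semi-implicit Euler step of the quad-model SDE, shared by the path and
// ensemble drivers.  Production/source terms explicit at t, linear losses
// implicit, diffusion = omega * (degradation + switching flux) at t, then
// clamp at zero.
static inline void sde_step_inline(const double *p, const double *sc,
                                   const double *om, double t, double dt,
                                   double sqdt, double *s, double *dw) {
  const double x = s[0], y = s[1], z = s[2];
  const double ks = kstar_at(sc, t);
  const double psi = sc[3];
  const double prodx = (p[13] + p[0] * x) / (1.0 + p[1] * x) / (1.0 + p[2] * y) *
                       (1.0 + p[16] * z) / (1.0 + p[12] * z) + psi * ks * z;
  const double prody = (p[14] + p[4] * y) / (1.0 + p[5] * y) / (1.0 + p[6] * x) /
                       (1.0 + p[12] * z);
  const double prodz = (p[15] + p[8] * z) / (1.0 + p[9] * z) /
                       (1.0 + p[10] * (x + y));
  const double dw1 = sqdt * R::norm_rand();
  const double dw2 = sqdt * R::norm_rand();
  const double dw3 = sqdt * R::norm_rand();
  if (dw) { dw[0] = dw1; dw[1] = dw2; dw[2] = dw3; }
  double xn = (x + dt * prodx + om[0] * (p[3] * x + psi * ks * z) * dw1) /
              (1.0 + dt * p[3]);
  double yn = (y + dt * prody + om[1] * p[7] * y * dw2) / (1.0 + dt * p[7]);
  double zn = (z + dt * prodz + om[2] * (p[11] + ks) * z * dw3) /
              (1.0 + dt * (p[11] + ks));
  s[0] = xn > 0.0 ? xn : 0.0;
  s[1] = yn > 0.0 ? yn : 0.0;
  s[2] = zn > 0.0 ? zn : 0.0;
}

// Single SDE trajectory; states saved every `save_every` steps (plus the
// initial state).  Optionally returns the Wiener increments of every step.
// [[Rcpp::export]]
List cpp_sde_path(NumericVector pars, NumericVector sched, NumericVector noise,
                  NumericVector init, double t_end, double dt, int save_every,
                  bool return_increments) {
  if (dt <= 0) stop("dt must be > 0");
  if (t_end <= 0) stop("t_end must be > 0");
  if (save_every < 1) save_every = 1;
  const int nstep = (int)std::round(t_end / dt);
  const int nsave = nstep / save_every + 1;
  NumericVector tout(nsave);
  NumericMatrix sout(nsave, 3);
  NumericMatrix incr = return_increments ? NumericMatrix(nstep, 3)
                                         : NumericMatrix(0, 3);
  double s[3] = {init[0], init[1], init[2]};
  double dw[3];
  const double sqdt = std::sqrt(dt);
  tout[0] = 0.0;
  for (int j = 0; j < 3; ++j) sout(0, j) = s[j];
  int isave = 1;
  for (int k = 0; k < nstep; ++k) {
    sde_step_inline(&pars[0], &sched[0], &noise[0], k * dt, dt, sqdt, s, dw);
    if (return_increments)
      for (int j = 0; j < 3; ++j) incr(k, j) = dw[j];
    if ((k + 1) % save_every == 0 && isave < nsave) {
      tout[isave] = (k + 1) * dt;
      for (int j = 0; j < 3; ++j) sout(isave, j) = s[j];
      ++isave;
    }
  }
  List out = List::create(_["time"] = tout, _["states"] = sout);
  if (return_increments) out["increments"] = incr;
  return out;
}

// Ensemble of independent replicates; returns the final states only.
// [[Rcpp::export]]
NumericMatrix cpp_sde_final(NumericVector pars, NumericVector sched,
                            NumericVector noise, NumericVector init,
                            double t_end, double dt, int n_reps) {
  if (dt <= 0) stop("dt must be > 0");
  const int nstep = (int)std::round(t_end / dt);
  const double sqdt = std::sqrt(dt);
  NumericMatrix out(n_reps, 3);
  for (int r = 0; r < n_reps; ++r) {
    double s[3] = {init[0], init[1], init[2]};
    for (int k = 0; k < nstep; ++k)
      sde_step_inline(&pars[0], &sched[0], &noise[0], k * dt, dt, sqdt, s, nullptr);
    for (int j = 0; j < 3; ++j) out(r, j) = s[j];
    if ((r & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Multistart damped Newton for the built-in vector fields (autonomous,
// k* = 0).  Each row of `starts` is one starting point; converged roots are
// returned row-wise (non-converged rows are NaN).  Negative components are
// projected to zero during iteration.  Jacobians by central differences,
// linear solves by Cramer's rule (dim <= 3).
// [[Rcpp::export]]
NumericMatrix cpp_newton_multistart(int model, NumericVector pars,
                                    NumericMatrix starts, double tol,
                                    int maxit) {
  const int dim = model_dim(model);
  if (starts.ncol() != dim) stop("starts have wrong dimension");
  const int ns = starts.nrow();
  NumericMatrix out(ns, dim);
  std::fill(out.begin(), out.end(), NA_REAL);
  double x[3], fx[3], fn[3], J[9], up[3], dn[3], fu[3], fd[3], step[3], xn[3];
  for (int r = 0; r < ns; ++r) {
    for (int j = 0; j < dim; ++j) x[j] = std::max(starts(r, j), 0.0);
    bool ok = false;
    for (int it = 0; it < maxit; ++it) {
      drift(model, &pars[0], nullptr, 0.0, x, fx);
      double nf = 0.0;
      for (int j = 0; j < dim; ++j) nf = std::max(nf, std::fabs(fx[j]));
      if (!std::isfinite(nf)) break;
      if (nf < tol) { ok = true; break; }
      // central-difference Jacobian
      for (int c = 0; c < dim; ++c) {
        double h = 1e-6 * std::max(1.0, std::fabs(x[c]));
        for (int j = 0; j < dim; ++j) { up[j] = x[j]; dn[j] = x[j]; }
        up[c] += h; dn[c] -= h;
        drift(model, &pars[0], nullptr, 0.0, up, fu);
        drift(model, &pars[0], nullptr, 0.0, dn, fd);
        for (int j = 0; j < dim; ++j) J[j * dim + c] = (fu[j] - fd[j]) / (2.0 * h);
      }
      // solve J step = fx
      bool solved = false;
      if (dim == 2) {
        double det = J[0] * J[3] - J[1] * J[2];
        if (std::fabs(det) > 1e-300) {
          step[0] = (fx[0] * J[3] - fx[1] * J[1]) / det;
          step[1] = (J[0] * fx[1] - J[2] * fx[0]) / det;
          solved = true;
        }
      } else {
        double det = J[0] * (J[4] * J[8] - J[5] * J[7]) -
                     J[1] * (J[3] * J[8] - J[5] * J[6]) +
                     J[2] * (J[3] * J[7] - J[4] * J[6]);
        if (std::fabs(det) > 1e-300) {
          double inv[9];
          inv[0] = (J[4] * J[8] - J[5] * J[7]) / det;
          inv[1] = (J[2] * J[7] - J[1] * J[8]) / det;
          inv[2] = (J[1] * J[5] - J[2] * J[4]) / det;
          inv[3] = (J[5] * J[6] - J[3] * J[8]) / det;
          inv[4] = (J[0] * J[8] - J[2] * J[6]) / det;
          inv[5] = (J[2] * J[3] - J[0] * J[5]) / det;
          inv[6] = (J[3] * J[7] - J[4] * J[6]) / det;
          inv[7] = (J[1] * J[6] - J[0] * J[7]) / det;
          inv[8] = (J[0] * J[4] - J[1] * J[3]) / det;
          for (int j = 0; j < dim; ++j)
            step[j] = inv[j * 3] * fx[0] + inv[j * 3 + 1] * fx[1] +
                      inv[j * 3 + 2] * fx[2];
          solved = true;
        }
      }
      if (!solved) break;
      bool finite_step = true;
      for (int j = 0; j < dim; ++j)
        if (!std::isfinite(step[j])) finite_step = false;
      if (!finite_step) break;
      // damped line search on the residual max-norm
      double lambda = 1.0;
      bool improved = false;
      for (int half = 0; half < 8; ++half) {
        for (int j = 0; j < dim; ++j)
          xn[j] = std::max(x[j] - lambda * step[j], 0.0);
        drift(model, &pars[0], nullptr, 0.0, xn, fn);
        double nn = 0.0;
        bool fin = true;
        for (int j = 0; j < dim; ++j) {
          if (!std::isfinite(fn[j])) { fin = false; break; }
          nn = std::max(nn, std::fabs(fn[j]));
        }
        if (fin && nn < nf) {
          for (int j = 0; j < dim; ++j) x[j] = xn[j];
          improved = true;
          break;
        }
        lambda /= 2.0;
      }
      if (!improved) { // take the full step; Newton may pass through a ridge
        for (int j = 0; j < dim; ++j) x[j] = std::max(x[j] - step[j], 0.0);
      }
    }
    if (!ok) { // final residual check after maxit
      drift(model, &pars[0], nullptr, 0.0, x, fx);
      double nf = 0.0;
      for (int j = 0; j < dim; ++j) nf = std::max(nf, std::fabs(fx[j]));
      ok = std::isfinite(nf) && nf < tol;
    }
    if (ok)
      for (int j = 0; j < dim; ++j) out(r, j) = x[j];
  }
  return out;
}

// Simulate many twonode parameter draws at once (ABC inner loop): each row of
// `par_mat` is an 8-parameter draw; returns the summed-absolute-deviation
// distance of each draw's trajectory (sampled at `times`) from `data`
// (matrix length(times) x 2).  Non-finite trajectories get distance Inf.
// [[Rcpp::export]]
NumericVector cpp_abc_distances(NumericMatrix par_mat, NumericMatrix data,
                                NumericVector init, NumericVector times,
                                double dt) {
  const int n = par_mat.nrow();
  const int m = times.size();
  if (data.nrow() != m || data.ncol() != 2) stop("data must be length(times) x 2");
  NumericVector out(n);
  NumericVector sched(0);
  for (int i = 0; i < n; ++i) {
    NumericVector p = par_mat(i, _);
    double rho = 0.0;
    bool bad = false;
    // inline RK4 over the sample grid
    double s[2] = {init[0], init[1]};
    double k1[2], k2[2], k3[2], k4[2], tmp[2];
    for (int j = 0; j < 2; ++j) {
      double d = data(0, j) - s[j];
      rho += std::fabs(d);
    }
    for (int ti = 1; ti < m && !bad; ++ti) {
      double t0 = times[ti - 1], t1 = times[ti];
      int nstep = (int)std::ceil((t1 - t0) / dt - 1e-12);
      double h = (t1 - t0) / nstep;
      for (int k = 0; k < nstep; ++k) {
        drift(2, &p[0], nullptr, 0.0, s, k1);
        for (int j = 0; j < 2; ++j) tmp[j] = s[j] + 0.5 * h * k1[j];
        drift(2, &p[0], nullptr, 0.0, tmp, k2);
        for (int j = 0; j < 2; ++j) tmp[j] = s[j] + 0.5 * h * k2[j];
        drift(2, &p[0], nullptr, 0.0, tmp, k3);
        for (int j = 0; j < 2; ++j) tmp[j] = s[j] + h * k3[j];
        drift(2, &p[0], nullptr, 0.0, tmp, k4);
        for (int j = 0; j < 2; ++j)
          s[j] += h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
        if (!std::isfinite(s[0]) || !std::isfinite(s[1])) { bad = true; break; }
      }
      if (!bad)
        for (int j = 0; j < 2; ++j) rho += std::fabs(data(ti, j) - s[j]);
    }
    out[i] = bad ? R_PosInf : rho;
    if ((i & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
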