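// Coordinate-descent solvers for the three sparsity-inducing selectors.
// All three minimize 0.5 * ||y - X theta||^2 plus a sparsity penalty (no 1/N
// factor) to a KKT tolerance, with warm starts supported for path fits.
// Each outer iteration does one full cyclic sweep, iterates on the active
// set (up to `inner_max` passes), recomputes the residual from scratch (so
// incremental-update roundoff cannot accumulate) and checks the KKT
// conditions exactly.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

static inline double dotcol(const double* x, const double* r, int n) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += x[i] * r[i];
  return s;
}

static inline void axpycol(double* r, const double* x, double a, int n) {
  for (int i = 0; i < n; ++i) r[i] -= x[i] * a;
}

// ---------------------------------------------------------------- Lasso ----
// [[Rcpp::export]]
List cpp_lasso(const NumericMatrix& X, const NumericVector& y, double lambda,
               double tol, int maxit, NumericVector theta0,
               int inner_max = 200) {
  const int n = X.nrow(), d = X.ncol();
  const double* Xp = &X[0];
  NumericVector theta = clone(theta0);
  std::vector<double> a(d);
  for (int j = 0; j < d; ++j) a[j] = dotcol(Xp + (size_t) j * n, Xp + (size_t) j * n, n);

  std::vector<double> r(n);
  auto fresh = [&]() {
    for (int i = 0; i < n; ++i) r[i] = y[i];
    for (int j = 0; j < d; ++j)
      if (theta[j] != 0.0) axpycol(r.data(), Xp + (size_t) j * n, theta[j], n);
  };
  fresh();

  const double scale = std::max(1.0, lambda);
  const double inner_tol = std::max(1e-12, 0.01 * tol) * scale;
  bool converged = false;
  int it = 0;
  double kkt = R_PosInf;

  for (it = 0; it < maxit && !converged; ++it) {
    for (int j = 0; j < d; ++j) {
      if (a[j] <= 0.0) { theta[j] = 0.0; continue; }
      const double* xj = Xp + (size_t) j * n;
      const double g = dotcol(xj, r.data(), n);
      const double tn = soft(g + a[j] * theta[j], lambda) / a[j];
      const double delta = tn - theta[j];
      if (delta != 0.0) { axpycol(r.data(), xj, delta, n); theta[j] = tn; }
    }
    for (int inner = 0; inner < inner_max; ++inner) {
      double maxstep = 0.0;
      for (int j = 0; j < d; ++j) {
        if (theta[j] == 0.0 || a[j] <= 0.0) continue;
        const double* xj = Xp + (size_t) j * n;
        const double g = dotcol(xj, r.data(), n);
        const double tn = soft(g + a[j] * theta[j], lambda) / a[j];
        const double delta = tn - theta[j];
        if (delta != 0.0) {
          axpycol(r.data(), xj, delta, n);
          theta[j] = tn;
          maxstep = std::max(maxstep, std::fabs(delta) * std::sqrt(a[j]));
        }
      }
      if (maxstep < inner_tol) break;
    }
    fresh();
    kkt = 0.0;
    for (int j = 0; j < d; ++j) {
      if (a[j] <= 0.0) continue;
      const double g = dotcol(Xp + (size_t) j * n, r.data(), n);
      const double v = (theta[j] != 0.0)
        ? std::fabs(g - lambda * ((theta[j] > 0) - (theta[j] < 0)))
        : std::max(0.0, std::fabs(g) - lambda);
      if (v > kkt) kkt = v;
    }
    if (kkt <= tol * scale) converged = true;
  }
  return List::create(_["theta"] = theta, _["iterations"] = it,
                      _["converged"] = converged, _["kkt"] = kkt);
}

// ---------------------------------------------------------- group Lasso ----
// groups: 0-based group id per column; weights: penalty factor per group
// (sqrt of group size). Block proximal-gradient updates with the block
// Lipschitz constant; singleton blocks are solved in closed form.
// [[Rcpp::export]]
List cpp_group_lasso(const NumericMatrix& X, const NumericVector& y,
                     const IntegerVector& groups, const NumericVector& weights,
                     double lambda, double tol, int maxit,
                     NumericVector theta0, int inner_max = 200) {
  const int n = X.nrow(), d = X.ncol();
  const int G = weights.size();
  const double* Xp = &X[0];
  NumericVector theta = clone(theta0);
  std::vector<std::vector<int> > gcols(G);
  for (int j = 0; j < d; ++j) gcols[groups[j]].push_back(j);

  std::vector<double> a(d);
  for (int j = 0; j < d; ++j) a[j] = dotcol(Xp + (size_t) j * n, Xp + (size_t) j * n, n);

  // block Lipschitz constants: largest eigenvalue of X_g' X_g (power method)
  std::vector<double> L(G, 0.0);
  for (int g = 0; g < G; ++g) {
    const std::vector<int>& cols = gcols[g];
    const int p = cols.size();
    if (p == 0) continue;
    if (p == 1) { L[g] = std::max(a[cols[0]], 1e-12); continue; }
    std::vector<double> M(p * p, 0.0);
    for (int u = 0; u < p; ++u)
      for (int v = u; v < p; ++v) {
        const double s = dotcol(Xp + (size_t) cols[u] * n,
                                Xp + (size_t) cols[v] * n, n);
        M[u * p + v] = M[v * p + u] = s;
      }
    double ev = 0.0;
    std::vector<double> w(p, 1.0 / std::sqrt((double) p)), w2(p);
    for (int itp = 0; itp < 200; ++itp) {
      double nrm = 0.0;
      for (int u = 0; u < p; ++u) {
        double s = 0.0;
        for (int v = 0; v < p; ++v) s += M[u * p + v] * w[v];
        w2[u] = s; nrm += s * s;
      }
      nrm = std::sqrt(nrm);
      if (nrm < 1e-300) { ev = 0.0; break; }
      for (int u = 0; u < p; ++u) w[u] = w2[u] / nrm;
      if (std::fabs(nrm - ev) < 1e-10 * std::max(1.0, nrm)) { ev = nrm; break; }
      ev = nrm;
    }
    L[g] = std::max(ev * 1.0001, 1e-12);
  }

  std::vector<double> r(n);
  auto fresh = [&]() {
    for (int i = 0; i < n; ++i) r[i] = y[i];
    for (int j = 0; j < d; ++j)
      if (theta[j] != 0.0) axpycol(r.data(), Xp + (size_t) j * n, theta[j], n);
  };
  fresh();

  const double scale = std::max(1.0, lambda);
  const double inner_tol = std::max(1e-12, 0.01 * tol) * scale;
  bool converged = false;
  int it = 0;
  double kkt = R_PosInf;

  auto block_update = [&](int g, int block_iter) -> double {
    const std::vector<int>& cols = gcols[g];
    const int p = cols.size();
    if (p == 0 || L[g] <= 1e-12) return 0.0;
    if (p == 1) {                       // closed-form singleton update
      const int j = cols[0];
      if (a[j] <= 0.0) { theta[j] = 0.0; return 0.0; }
      const double* xj = Xp + (size_t) j * n;
      const double g1 = dotcol(xj, r.data(), n);
      const double tn = soft(g1 + a[j] * theta[j], lambda * weights[g]) / a[j];
      const double delta = tn - theta[j];
      if (delta != 0.0) { axpycol(r.data(), xj, delta, n); theta[j] = tn; }
      return std::fabs(delta) * std::sqrt(a[j]);
    }
    const double step = 1.0 / L[g];
    const double thr = lambda * weights[g] * step;
    double total_change = 0.0;
    std::vector<double> u(p);
    for (int inner = 0; inner < block_iter; ++inner) {
      double nrm = 0.0;
      for (int c = 0; c < p; ++c) {
        const int j = cols[c];
        const double grad = dotcol(Xp + (size_t) j * n, r.data(), n);
        u[c] = theta[j] + step * grad;
        nrm += u[c] * u[c];
      }
      nrm = std::sqrt(nrm);
      const double sc = (nrm > thr) ? (1.0 - thr / nrm) : 0.0;
      double change = 0.0;
      for (int c = 0; c < p; ++c) {
        const int j = cols[c];
        const double tn = sc * u[c];
        const double delta = tn - theta[j];
        if (delta != 0.0) {
          axpycol(r.data(), Xp + (size_t) j * n, delta, n);
          theta[j] = tn;
          change = std::max(change, std::fabs(delta));
        }
      }
      total_change = std::max(total_change, change);
      if (change < inner_tol * 0.1) break;
    }
    return total_change;
  };

  std::vector<bool> active(G, false);

  for (it = 0; it < maxit && !converged; ++it) {
    for (int g = 0; g < G; ++g) block_update(g, inner_max);
    for (int g = 0; g < G; ++g) {
      active[g] = false;
      for (size_t c = 0; c < gcols[g].size(); ++c)
        if (theta[gcols[g][c]] != 0.0) { active[g] = true; break; }
    }
    for (int inner = 0; inner < inner_max; ++inner) {
      double maxstep = 0.0;
      for (int g = 0; g < G; ++g)
        if (active[g]) maxstep = std::max(maxstep, block_update(g, inner_max));
      if (maxstep < inner_tol) break;
    }
    fresh();
    kkt = 0.0;
    for (int g = 0; g < G; ++g) {
      const std::vector<int>& cols = gcols[g];
      const int p = cols.size();
      if (p == 0 || L[g] <= 1e-12) continue;
      double tnorm = 0.0;
      std::vector<double> gr(p);
      for (int c = 0; c < p; ++c) {
        const int j = cols[c];
        gr[c] = dotcol(Xp + (size_t) j * n, r.data(), n);
        tnorm += theta[j] * theta[j];
      }
      tnorm = std::sqrt(tnorm);
      double v;
      if (tnorm > 0.0) {
        double s2 = 0.0;
        for (int c = 0; c < p; ++c) {
          const double resid = gr[c] - lambda * weights[g] * theta[cols[c]] / tnorm;
          s2 += resid * resid;
        }
        v = std::sqrt(s2);
      } else {
        double gnorm = 0.0;
        for (int c = 0; c < p; ++c) gnorm += gr[c] * gr[c];
        v = std::max(0.0, std::sqrt(gnorm) - lambda * weights[g]);
      }
      if (v > kkt) kkt = v;
    }
    if (kkt <= tol * scale) converged = true;
  }
  return List::create(_["theta"] = theta, _["iterations"] = it,
                      _["converged"] = converged, _["kkt"] = kkt);
}

// ------------------------------------------------------ Multi-Task Lasso ----
// l2,1 penalty on the rows of Theta (d x T); closed-form row updates.
// [[Rcpp::export]]
List cpp_mtl(const NumericMatrix& X, const NumericMatrix& Y, double lambda,
             double tol, int maxit, NumericMatrix Theta0, int inner_max = 200) {
  const int n = X.nrow(), d = X.ncol(), T = Y.ncol();
  const double* Xp = &X[0];
  NumericMatrix Theta = clone(Theta0);
  double* Tp = &Theta[0];
  std::vector<double> a(d);
  for (int j = 0; j < d; ++j) a[j] = dotcol(Xp + (size_t) j * n, Xp + (size_t) j * n, n);

  NumericMatrix R(n, T);
  double* Rp = &R[0];
  auto fresh_R = [&]() {
    for (int t = 0; t < T; ++t) {
      double* rc = Rp + (size_t) t * n;
      const double* yc = &Y[0] + (size_t) t * n;
      for (int i = 0; i < n; ++i) rc[i] = yc[i];
      for (int j = 0; j < d; ++j) {
        const double th = Tp[(size_t) t * d + j];
        if (th != 0.0) axpycol(rc, Xp + (size_t) j * n, th, n);
      }
    }
  };
  fresh_R();

  const double scale = std::max(1.0, lambda);
  const double inner_tol = std::max(1e-12, 0.01 * tol) * scale;
  bool converged = false;
  int it = 0;
  double kkt = R_PosInf;
  std::vector<double> z(T);

  auto row_update = [&](int j) -> double {
    if (a[j] <= 0.0) {
      for (int t = 0; t < T; ++t) Tp[(size_t) t * d + j] = 0.0;
      return 0.0;
    }
    const double* xj = Xp + (size_t) j * n;
    double znorm = 0.0;
    for (int t = 0; t < T; ++t) {
      const double g = dotcol(xj, Rp + (size_t) t * n, n);
      z[t] = g + a[j] * Tp[(size_t) t * d + j];
      znorm += z[t] * z[t];
    }
    znorm = std::sqrt(znorm);
    const double sc = (znorm > lambda) ? (1.0 - lambda / znorm) / a[j] : 0.0;
    double maxdelta = 0.0;
    for (int t = 0; t < T; ++t) {
      const double tn = sc * z[t];
      const double delta = tn - Tp[(size_t) t * d + j];
      if (delta != 0.0) {
        axpycol(Rp + (size_t) t * n, xj, delta, n);
        Tp[(size_t) t * d + j] = tn;
        maxdelta = std::max(maxdelta, std::fabs(delta) * std::sqrt(a[j]));
      }
    }
    return maxdelta;
  };

  for (it = 0; it < maxit && !converged; ++it) {
    for (int j = 0; j < d; ++j) row_update(j);
    for (int inner = 0; inner < inner_max; ++inner) {
      double maxstep = 0.0;
      for (int j = 0; j < d; ++j) {
        bool act = false;
        for (int t = 0; t < T; ++t)
          if (Tp[(size_t) t * d + j] != 0.0) { act = true; break; }
        if (act) maxstep = std::max(maxstep, row_update(j));
      }
      if (maxstep < inner_tol) break;
    }
    fresh_R();
    kkt = 0.0;
    for (int j = 0; j < d; ++j) {
      if (a[j] <= 0.0) continue;
      const double* xj = Xp + (size_t) j * n;
      double rnorm = 0.0;
      for (int t = 0; t < T; ++t) {
        const double th = Tp[(size_t) t * d + j];
        rnorm += th * th;
      }
      rnorm = std::sqrt(rnorm);
      double v;
      if (rnorm > 0.0) {
        double s2 = 0.0;
        for (int t = 0; t < T; ++t) {
          const double g = dotcol(xj, Rp + (size_t) t * n, n);
          const double resid = g - lambda * Tp[(size_t) t * d + j] / rnorm;
          s2 += resid * resid;
        }
        v = std::sqrt(s2);
      } else {
        double gnorm = 0.0;
        for (int t = 0; t < T; ++t) {
          const double g = dotcol(xj, Rp + (size_t) t * n, n);
          gnorm += g * g;
        }
        v = std::max(0.0, std::sqrt(gnorm) - lambda);
      }
      if (v > kkt) kkt = v;
    }
    if (kkt <= tol * scale) converged = true;
  }
  return List::create(_["theta"] = Theta, _["iterations"] = it,
                      _["converged"] = converged, _["kkt"] = kkt);
}
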