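// Solver for the shared-information constrained optimization.
//
// SI(Y; {X, Z}) = max over q(x,y,z) preserving p(x,y) and p(z,y) of
//   [ I_q(X;Y) - I_q(X;Y|Z) ].
// Because both target-linked pairwise marginals are fixed, I_q(X;Y),
// H_q(Y|Z) and H_q(Y) are constants on the feasible set, and the problem
// reduces to maximizing the concave functional
//   f(q) = H_q(Y | X, Z) = -sum q log q(y | x, z)
// over a product of per-y-slice transportation polytopes (row sums p(x,y),
// column sums p(z,y)). Projected gradient ascent with Armijo backtracking;
// the Euclidean projection onto each polytope is computed with Dykstra's
// alternating projections between the affine marginal constraints (closed
// form) and the nonnegative orthant.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double EPS = 1e-300;

// index helper: q stored as slices over y, each slice nx x nz column-major
static inline int IDX(int x, int z, int nx) { return x + nx * z; }

// projection of one slice onto the affine set {M1 = r, M^T 1 = c}
static void proj_affine(std::vector<double>& M, const std::vector<double>& r,
                        const std::vector<double>& c, int nx, int nz) {
  std::vector<double> rowsum(nx, 0.0), colsum(nz, 0.0);
  double total = 0.0, target = 0.0;
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      double v = M[IDX(x, z, nx)];
      rowsum[x] += v; colsum[z] += v; total += v;
    }
  for (int x = 0; x < nx; ++x) target += r[x];
  double D = target - total;
  // M' = M + u 1^T + 1 v^T with the symmetric split of the total deficit
  std::vector<double> u(nx), v(nz);
  for (int x = 0; x < nx; ++x)
    u[x] = (r[x] - rowsum[x] - D / (2.0 * nx)) / nz;
  for (int z = 0; z < nz; ++z)
    v[z] = (c[z] - colsum[z] - D / (2.0 * nz)) / nx;
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      M[IDX(x, z, nx)] += u[x] + v[z];
}

// feasibility residual of a slice: worst marginal violation
static double marg_residual(const std::vector<double>& M,
                            const std::vector<double>& r,
                            const std::vector<double>& c, int nx, int nz) {
  double res = 0.0;
  for (int x = 0; x < nx; ++x) {
    double s = 0.0;
    for (int z = 0; z < nz; ++z) s += M[IDX(x, z, nx)];
    res = std::max(res, std::fabs(s - r[x]));
  }
  for (int z = 0; z < nz; ++z) {
    double s = 0.0;
    for (int x = 0; x < nx; ++x) s += M[IDX(x, z, nx)];
    res = std::max(res, std::fabs(s - c[z]));
  }
  return res;
}

// Dykstra projection of one slice onto {affine} \cap {M >= 0}; residual
// driven, with an alternating-projection fallback that guarantees a feasible
// (if slightly suboptimal) point near degenerate faces
static void proj_polytope(std::vector<double>& M, const std::vector<double>& r,
                          const std::vector<double>& c, int nx, int nz,
                          int inner_it = 2000, double tol = 1e-12) {
  int n = nx * nz;
  // Dykstra: the affine set needs no correction vector, the orthant does
  std::vector<double> qcorr(n, 0.0), y(n);
  for (int it = 0; it < inner_it; ++it) {
    for (int i = 0; i < n; ++i) y[i] = M[i];
    proj_affine(y, r, c, nx, nz);
    for (int i = 0; i < n; ++i) {
      double t = y[i] + qcorr[i];
      double clipped = t > 0.0 ? t : 0.0;
      qcorr[i] = t - clipped;
      M[i] = clipped;
    }
    if ((it & 7) == 7 && marg_residual(M, r, c, nx, nz) < tol) break;
  }
  // von Neumann alternating projections to drive the residual down; this
  // converges to a feasible point of the intersection
  for (int it = 0; it < 400; ++it) {
    if (marg_residual(M, r, c, nx, nz) < tol) break;
    proj_affine(M, r, c, nx, nz);
    for (int i = 0; i < n; ++i) if (M[i] < 0.0) M[i] = 0.0;
  }
  // final exactness of the affine constraints; clip only cosmetic negatives
  proj_affine(M, r, c, nx, nz);
  for (int i = 0; i < n; ++i) if (M[i] < -1e-9) M[i] = 0.0;
  for (int i = 0; i < n; ++i) if (M[i] < 0.0) M[i] = 0.0;
}

// [[Rcpp::export]]
NumericMatrix dykstra_project_cpp(NumericMatrix M, NumericVector r,
                                  NumericVector c) {
  int nx = M.nrow(), nz = M.ncol();
  std::vector<double> m(nx * nz);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) m[IDX(x, z, nx)] = M(x, z);
  std::vector<double> rv(r.begin(), r.end()), cv(c.begin(), c.end());
  proj_polytope(m, rv, cv, nx, nz);
  NumericMatrix out(nx, nz);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) out(x, z) = m[IDX(x, z, nx)];
  return out;
}

// objective f(q) = -sum q log q + sum q_xz log q_xz   (nats)
static double objective(const std::vector<std::vector<double> >& q,
                        int nx, int ny, int nz) {
  std::vector<double> qxz(nx * nz, 0.0);
  double f = 0.0;
  for (int y = 0; y < ny; ++y)
    for (int i = 0; i < nx * nz; ++i) {
      double v = q[y][i];
      qxz[i] += v;
      if (v > EPS) f -= v * std::log(v);
    }
  for (int i = 0; i < nx * nz; ++i)
    if (qxz[i] > EPS) f += qxz[i] * std::log(qxz[i]);
  return f;
}

// [[Rcpp::export]]
List si_solver_cpp(NumericMatrix p_xy, NumericMatrix p_zy,
                   int restarts = 10, int maxit = 2000,
                   double tol = 1e-10, double jitter = 0.25) {
  int nx = p_xy.nrow(), ny = p_xy.ncol(), nz = p_zy.nrow();
  if (p_zy.ncol() != ny) stop("p_xy and p_zy must share the target dimension");
  std::vector<double> py(ny, 0.0);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) py[y] += p_xy(x, y);

  double best = -1e300;
  bool any_converged = false;
  int total_iters = 0;
  std::vector<std::vector<double> > qbest;

  for (int rs = 0; rs < restarts; ++rs) {
    // init: conditional independence given y, optionally jittered
    std::vector<std::vector<double> > q(ny, std::vector<double>(nx * nz, 0.0));
    for (int y = 0; y < ny; ++y) {
      if (py[y] <= 0.0) continue;
      for (int z = 0; z < nz; ++z)
        for (int x = 0; x < nx; ++x)
          q[y][IDX(x, z, nx)] = p_xy(x, y) * p_zy(z, y) / py[y];
      if (rs > 0) {
        std::vector<double> r(nx), c(nz);
        for (int x = 0; x < nx; ++x) r[x] = p_xy(x, y);
        for (int z = 0; z < nz; ++z) c[z] = p_zy(z, y);
        for (int i = 0; i < nx * nz; ++i)
          q[y][i] *= (1.0 + jitter * (R::runif(-1.0, 1.0)));
        proj_polytope(q[y], r, c, nx, nz);
      }
    }

    double f = objective(q, nx, ny, nz);
    double step = 0.25;
    bool converged = false;
    std::vector<double> qxz(nx * nz);
    std::vector<std::vector<double> > qnew(ny, std::vector<double>(nx * nz));
    std::vector<std::vector<double> > qprev = q; // for heavy-ball momentum
    const double beta = 0.85;

    for (int it = 0; it < maxit; ++it) {
      ++total_iters;
      std::fill(qxz.begin(), qxz.end(), 0.0);
      for (int y = 0; y < ny; ++y)
        for (int i = 0; i < nx * nz; ++i) qxz[i] += q[y][i];
      // gradient of f: -log q(y | x, z), floored for empty cells; the step
      // is scaled by the gradient sup-norm so the proposal stays within a
      // bounded distance of the polytope (keeps the projection accurate)
      std::vector<std::vector<double> > grad(ny, std::vector<double>(nx * nz, 0.0));
      double gmax = 1.0;
      for (int y = 0; y < ny; ++y) {
        if (py[y] <= 0.0) continue;
        for (int i = 0; i < nx * nz; ++i) {
          double qi = q[y][i] > 1e-12 ? q[y][i] : 1e-12;
          double mi = qxz[i] > 1e-12 ? qxz[i] : 1e-12;
          grad[y][i] = std::log(mi) - std::log(qi);
          if (std::fabs(grad[y][i]) > gmax) gmax = std::fabs(grad[y][i]);
        }
      }
      bool improved = false;
      double fnew = f;
      for (int half = 0; half < 40; ++half) {
        double eta = step / gmax;
        for (int y = 0; y < ny; ++y) {
          if (py[y] <= 0.0) { qnew[y] = q[y]; continue; }
          std::vector<double> r(nx), c(nz);
          for (int x = 0; x < nx; ++x) r[x] = p_xy(x, y);
          for (int z = 0; z < nz; ++z) c[z] = p_zy(z, y);
          for (int i = 0; i < nx * nz; ++i)
            qnew[y][i] = q[y][i] + eta * grad[y][i] +
              beta * (q[y][i] - qprev[y][i]);
          proj_polytope(qnew[y], r, c, nx, nz);
        }
        fnew = objective(qnew, nx, ny, nz);
        if (fnew > f + 1e-16) { improved = true; break; }
        step *= 0.5;
        if (step < 1e-14) break;
      }
      if (!improved) {
        // if momentum is active, drop it and try plain gradient steps before
        // declaring convergence
        bool had_momentum = false;
        for (int y = 0; y < ny && !had_momentum; ++y)
          for (int i = 0; i < nx * nz; ++i)
            if (q[y][i] != qprev[y][i]) { had_momentum = true; break; }
        if (had_momentum) { qprev = q; step = 0.25; continue; }
        converged = true; break;
      }
      double gain = fnew - f;
      qprev.swap(q);
      q.swap(qnew);
      f = fnew;
      step *= 1.8; if (step > 1.0) step = 1.0;
      if (gain < tol && it > 20) { converged = true; break; }
    }
    if (f > best) { best = f; qbest = q; }
    if (converged) any_converged = true;
  }

  // flatten q* as an array [x, y, z]
  NumericVector qout(nx * ny * nz);
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x)
        qout[x + nx * y + nx * ny * z] =
          qbest.empty() ? NA_REAL : qbest[y][IDX(x, z, nx)];
  qout.attr("dim") = IntegerVector::create(nx, ny, nz);

  return List::create(_["h_y_given_xz"] = best,
                      _["converged"] = any_converged,
                      _["iterations"] = total_iters,
                      _["q"] = qout);
}
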